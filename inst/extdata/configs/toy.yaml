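# Fast CI-scale configuration (n = 100)
population:
  label: preterm
  n: 100
  seed: 7
  vd_policy: fixed
regimens:
  - name: extended
    dose_per_kg: 6
    interval: 48
mic:
  min: 0.25
  max: 2.0
  step: 0.25
  reference: 1
solver:
  mode: mass_conserving
  engine: analytic
  dt: 0.25
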