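# Term neonates: conventional vs extended-interval gentamicin dosing
population:
  label: term
  n: 1000
  seed: 20220902
  vd_policy: fixed
regimens:
  - name: conventional
    dose_per_kg: 4
    interval: 24
  - name: extended
    dose_per_kg: 6
    interval: 36
mic:
  min: 0.05
  max: 2.0
  step: 0.05
  reference: 1
solver:
  mode: mass_conserving
  engine: analytic
  dt: 0.1
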