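# gentapbpk

Minimal physiologically-based pharmacokinetic (PBPK) modelling and
PK/PD dosing evaluation of gentamicin in preterm and term neonates.

Gentamicin is the empirical aminoglycoside of choice for suspected
early-onset neonatal sepsis. Its clearance is renal, neonatal glomerular
filtration varies strongly with gestational age, and the therapeutic
window is narrow: efficacy needs peak-to-MIC ratios
`Cmax/MIC >= 8` and time above MIC `T>MIC >= 60%` of the dosing
interval, while troughs `Cmin >= 2 mg/L` or peaks `Cmax >= 25 mg/L`
signal toxicity risk. This package is for pharmacometricians and
clinical-pharmacology researchers who want a small, fully inspectable
model of that trade-off.

## The model

Four states — a well-stirred heart chamber, a flow-limited kidney, a
lumped flow-limited rest-of-tissues compartment and the blood pool
(volume = the distribution volume V_d) — with elimination by glomerular
filtration corrected for 21% tubular reabsorption:

    Q_e = TBW · GFR · (1 − 0.21)                       [mL/min]

    V_h dC_h/dt = Q_h (C_b − C_h)
    V_k dC_k/dt = Q_k C_b − (Q_k + Q_e) C_k/P_k
    V_r dC_r/dt = Q_r C_b − Q_r C_r/P_r
    V_d dC_b/dt = R(t) + Q_h C_h + Σ Q_i C_i/P_i − Q_h C_b − Σ Q_i C_b

`R(t)` is a 0.5-h rectangular infusion pulse per dosing interval. The
final blood-outflow term closes the mass balance (the default
`mass_conserving` mode; the literal `as_printed` transcription without
it has net positive feedback and is detected as divergent rather than
simulated silently). Around the core sit seeded log-normal Monte Carlo
populations (CVs: body weight 20%, kidney flow 20%, cardiac output 24%,
GFR 40%), probability-of-target-attainment (PTA) evaluation over MIC
grids, MPE/AFE/AAFE predictive metrics with visual predictive checks,
iterative two-stage (ITS) estimation of GFR from sparse 2 h / 24 h TDM
data, and a synthetic TDM-study generator (31 preterm + 16 term
virtual subjects) so everything runs without clinical records.

## Worked example

```r
library(gentapbpk)

p   <- pbpk_preset("preterm")          # 1.73 kg, GFR 1.31 mL/min/kg, Vd 0.52 L/kg
reg <- dosing_regimen(6, interval = 48)   # extended interval, 0.5-h infusion
prof <- simulate_profile(p, reg)
prof
#> concentration profile: 481 points on [0, 48] h, Cmax 4.253 mg/L
compute_indices(prof, mic = 1)[c("Cmax", "Cmin", "t_above_mic")]
#> $Cmax        4.253099
#> $Cmin        0.7182961
#> $t_above_mic 79.48695
flow_limited_clearance(p)              # closed-form dose/AUC cross-check
#> [1] 0.09671749

coh   <- sample_cohort(population_spec("preterm", n = 1000, seed = 42))
profs <- simulate_cohort(coh, reg)     # exact analytic engine, ~10 s
res   <- pta(profs, mic_grid = c(0.5, 1, 2))
res
#> PTA over 1000 subjects, interval 48 h
#>   at MIC 1 mg/L: cmax_mic 0.0%, t_above_mic 84.4%
#>   toxicity: Cmin 0.5%, Cmax 0.0%
classify_regimen(res, mic = 1)[c("effective", "safe")]
#> $effective FALSE
#> $safe      TRUE
```

Reading: with this model structure a 6 mg/kg dose peaks near 4.3 mg/L
(the blood pool equilibrates with ~1.1 L/kg of tissue during the
infusion), so the peak-ratio target at MIC 1 mg/L is not attained while
84% of subjects stay above the MIC for ≥ 60% of the 48-h interval, and
both toxicity criteria are comfortably rare (≤ 0.5%) — the regimen
classifies as safe but not effective on the peak criterion.

Estimation from synthetic TDM data:

```r
ds  <- generate_tdm(synthetic_study_spec(seed = 7))   # 47 subjects, 91 samples
fit <- its_fit(ds$data, group = "preterm")
fit
#> ITS fit (preterm, 31 subjects): GFR mean 1.286, omega 0.341, sigma 0.0465
#>   converged after 7 iterations; 0 below-LLOQ observation(s) excluded
```

The generating truth was GFR mean 1.31 mL/min/kg (CV 40%): recovered
within 2% here.

Config-driven pipelines (`run_simulate`, `run_pta`, `run_validate`,
`run_estimate`, `run_synth`) reproduce the full experiments from the
YAML presets in `inst/extdata/configs/` (`study-preterm.yaml`,
`study-term.yaml`, `toy.yaml`), each writing tidy CSV/JSON plus a
provenance sidecar; `inst/scripts/gentapbpk.R` wraps them for the shell.

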