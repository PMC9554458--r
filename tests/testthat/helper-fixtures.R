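# shared fixtures: closed-form profiles and small cohorts built in code

# mono-exponential decay profile C(t) = C0 * exp(-k t) on a uniform grid
expo_profile <- function(C0, k, t_end = 24, dt = 0.5) {
  tt <- seq(0, t_end, by = dt)
  concentration_profile(tt, C0 * exp(-k * tt))
}

# constant-concentration profile
flat_profile <- function(C, t_end = 24, dt = 1) {
  tt <- seq(0, t_end, by = dt)
  concentration_profile(tt, rep(C, length(tt)))
}

preterm_regimen_ext <- function() dosing_regimen(6, interval = 48)
preterm_regimen_conv <- function() dosing_regimen(4, interval = 24)

small_cohort <- function(n = 30, seed = 101, label = "preterm", ...)
  sample_cohort(population_spec(label, n = n, seed = seed, ...))

# absolute drug amount in the body along a simulated profile, mg
body_amount <- function(profile) {
  a <- gentapbpk:::as_absolute(profile$params)
  ts <- profile$tissues
  a$Vh * ts$Ch + a$Vk * ts$Ck + a$Vr * ts$Cr + a$Vd * profile$Cb
}

# administered amount up to each output time, mg (linear infusion ramp)
administered_amount <- function(profile) {
  reg <- profile$regimen
  rate <- reg$dose_per_kg * profile$params$TBW / reg$infusion_duration
  Reduce(`+`, lapply(seq_len(reg$n_doses) - 1L, function(k) {
    t0 <- k * reg$interval
    rate * pmin(pmax(profile$times - t0, 0), reg$infusion_duration)
  }))
}
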