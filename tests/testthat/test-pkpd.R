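test_that("indices of a constant profile are the constant", {
  idx <- compute_indices(flat_profile(10), interval = 24, mic = 1)
  expect_equal(idx$Cmax, 10)
  expect_equal(idx$Cmin, 10)
  expect_equal(idx$t_above_mic, 100)
})

test_that("indices of a mono-exponential match the closed form", {
  # C(t) = 12 exp(-0.1 t): crossing of MIC 2 at ln(6)/0.1 = 17.918 h
  prof <- expo_profile(12, 0.1, t_end = 24, dt = 0.01)
  idx <- compute_indices(prof, interval = 24, mic = 2)
  expect_equal(idx$Cmax, 12)
  expect_equal(idx$Cmin, 12 * exp(-2.4), tolerance = 1e-6) # 1.0888
  expect_equal(idx$t_above_mic, 100 * log(6) / 0.1 / 24, tolerance = 1e-4)
  # MIC 1: crossing time 24.85 h lies beyond the interval
  expect_equal(compute_indices(prof, interval = 24, mic = 1)$t_above_mic,
               100)
  expect_warning(
    idx0 <- compute_indices(prof, interval = 24, mic = 0), "non-positive")
  expect_equal(idx0$t_above_mic, 100)
  expect_error(compute_indices(prof, interval = 48), "cover")
})

test_that("PTA counts attainment fractions over identical subjects", {
  profs <- replicate(5, flat_profile(10), simplify = FALSE)
  res <- pta(profs, mic_grid = c(1, 2), interval = 24)
  get <- function(m, crit)
    res$pta$pta_percent[res$pta$mic == m & res$pta$criterion == crit]
  expect_equal(get(1, "cmax_mic"), 100) # ratio 10 >= 8
  expect_equal(get(2, "cmax_mic"), 0)   # ratio 5 < 8
  expect_equal(get(2, "t_above_mic"), 100)
  expect_equal(unname(res$toxicity["cmin"]), 100) # flat 10 >= 2
  expect_equal(unname(res$toxicity["cmax"]), 0)   # 10 < 25
  expect_error(pta(list(), interval = 24), "empty")
})

test_that("PTA matches the log-normal CDF oracle at n = 1e4", {
  n <- 1e4
  mlog <- log(10); slog <- 0.3
  c0 <- withr::with_seed(2024, stats::rlnorm(n, mlog, slog))
  profs <- lapply(c0, function(x) expo_profile(x, 0.05, t_end = 24, dt = 3))
  res <- pta(profs, mic_grid = c(0.5, 1, 1.5), interval = 24)
  for (m in c(0.5, 1, 1.5)) {
    oracle <- 100 * stats::pnorm((mlog - log(8 * m)) / slog)
    got <- res$pta$pta_percent[res$pta$mic == m &
                                 res$pta$criterion == "cmax_mic"]
    # binomial error: 4 * sqrt(p(1-p)/n) * 100 < 2 percentage points
    expect_lt(abs(got - oracle), 2)
  }
})

test_that("PTA is exactly monotone in MIC and order-invariant on a fixed cohort", {
  coh <- small_cohort(n = 40)
  profs <- simulate_cohort(coh, preterm_regimen_ext(), dt = 0.25)
  res <- pta(profs, mic_grid = seq(0.25, 2, by = 0.25))
  for (crit in c("cmax_mic", "t_above_mic")) {
    cur <- res$pta[res$pta$criterion == crit, ]
    expect_true(all(diff(cur$pta_percent[order(cur$mic)]) <= 0))
  }
  res2 <- pta(rev(profs), mic_grid = seq(0.25, 2, by = 0.25))
  expect_equal(res2$pta$pta_percent, res$pta$pta_percent)
  expect_true(all(res$pta$pta_percent >= 0 & res$pta$pta_percent <= 100))
})

test_that("dose and MIC scale together under model linearity", {
  coh <- small_cohort(n = 25, seed = 55)
  lo <- simulate_cohort(coh, dosing_regimen(4, 24), dt = 0.25)
  hi <- simulate_cohort(coh, dosing_regimen(8, 24), dt = 0.25)
  pta_lo <- pta(lo, mic_grid = c(0.5, 1))$pta
  pta_hi <- pta(hi, mic_grid = c(1, 2))$pta
  expect_equal(
    pta_lo$pta_percent[pta_lo$mic == 0.5 & pta_lo$criterion == "cmax_mic"],
    pta_hi$pta_percent[pta_hi$mic == 1 & pta_hi$criterion == "cmax_mic"])
  expect_equal(
    pta_lo$pta_percent[pta_lo$mic == 1 & pta_lo$criterion == "cmax_mic"],
    pta_hi$pta_percent[pta_hi$mic == 2 & pta_hi$criterion == "cmax_mic"])
})

test_that("MIC breakpoints invert the PTA curve", {
  mk_res <- function(mics, ptas, n = 1000) {
    structure(list(
      pta = data.frame(mic = mics, criterion = "cmax_mic",
                       pta_percent = ptas),
      toxicity = c(cmin = 0, cmax = 0), n = n,
      criteria = pkpd_criteria(), interval = 24), class = "pta_result")
  }
  # clean step curve
  step <- mk_res(seq(0.2, 2, 0.2), ifelse(seq(0.2, 2, 0.2) <= 1, 100, 0))
  expect_equal(mic_breakpoint(step), 1.0)
  # nothing attains the threshold
  none <- mk_res(c(0.5, 1), c(50, 20))
  out <- mic_breakpoint(none)
  expect_true(is.na(out))
  expect_true(attr(out, "none_found"))
  # non-monotone beyond MC noise warns and uses the last down-crossing
  wob <- mk_res(c(0.5, 1, 1.5, 2), c(95, 40, 95, 10))
  expect_warning(bp <- mic_breakpoint(wob), "non-monotone")
  expect_equal(bp, 1.5)
  # Monte Carlo curve agrees with the analytic CDF inversion to one step
  n <- 1e4
  c0 <- withr::with_seed(31, stats::rlnorm(n, log(10), 0.3))
  profs <- lapply(c0, function(x) expo_profile(x, 0.05, t_end = 24, dt = 3))
  res <- pta(profs, mic_grid = seq(0.05, 2, by = 0.05), interval = 24)
  bp_mc <- mic_breakpoint(res, "cmax_mic", 90)
  bp_true <- exp(log(10 / 8) - 0.3 * stats::qnorm(0.90)) # 0.851
  expect_lt(abs(bp_mc - 0.85), 0.05 + 1e-9) # within one grid step
  expect_equal(round(bp_true, 2), 0.85)
})

test_that("regimen classification applies inclusive decision thresholds", {
  mk <- function(eff1, eff2, tox1, tox2) {
    structure(list(
      pta = data.frame(mic = 1, criterion = c("cmax_mic", "t_above_mic"),
                       pta_percent = c(eff1, eff2)),
      toxicity = c(cmin = tox1, cmax = tox2), n = 1000,
      criteria = pkpd_criteria(), interval = 48), class = "pta_result")
  }
  good <- classify_regimen(mk(99.9, 95, 5.9, 6.9))
  expect_true(good$effective)
  expect_true(good$safe)
  expect_false(classify_regimen(mk(89.9, 95, 5, 5))$effective) # strict >=
  expect_true(classify_regimen(mk(95, 95, 10.0, 10.0))$safe)   # inclusive <=
  expect_false(classify_regimen(mk(95, 95, 10.1, 5))$safe)
  expect_error(classify_regimen(mk(95, 95, 5, 5), mic = 0.7), "grid")
})

test_that("PTA curves export as tidy CSV", {
  profs <- replicate(3, flat_profile(10), simplify = FALSE)
  res <- pta(profs, mic_grid = c(1, 2), interval = 24)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pta_csv(res, path)
  back <- utils::read.csv(path)
  expect_named(back, c("mic", "criterion", "pta_percent"))
  expect_equal(nrow(back), 4)
})
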