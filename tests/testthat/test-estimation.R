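# deterministic one-subject fixture simulated at a known GFR
subject_fixture <- function(gfr = 1.31, tbw = 1.73, dose = 6,
                            interval = 48, times = c(2, 24)) {
  s <- list(id = 1L, TBW = tbw, dose_per_kg = dose, infusion_h = 0.5,
            interval = interval)
  conc <- gentapbpk:::predict_subject(gfr, "GFR", s, times,
                                      pbpk_preset("preterm"))
  list(subject = s, obs = data.frame(time = times, conc = conc))
}

test_that("MAP fit recovers the truth from noise-free data", {
  model <- population_model(mean = 1.31, cv = 0.40, sigma = 0.10)
  # truth at the prior mode (the moment-matched log-normal prior is
  # centred at exp(mu), the median, below the arithmetic mean)
  truth <- exp(model$mu)
  fx <- subject_fixture(gfr = truth)
  fit <- map_individual(fx$subject, fx$obs, model, pbpk_preset("preterm"))
  expect_equal(fit$value, truth, tolerance = 1e-3)
  expect_true(fit$converged)
  expect_gt(fit$var, 0)
  # truth far from the prior: tight data + weak prior still recovers it
  fx2 <- subject_fixture(gfr = 2.62)
  weak <- population_model(mean = 1.31, cv = 1.0, sigma = 0.02)
  fit2 <- map_individual(fx2$subject, fx2$obs, weak,
                         pbpk_preset("preterm"))
  expect_lt(abs(fit2$value - 2.62) / 2.62, 0.05)
})

test_that("MAP degenerates gracefully to the prior", {
  model <- population_model(mean = 1.31, cv = 0.40, sigma = 0.10)
  none <- map_individual(list(id = 1), data.frame(time = numeric(),
                                                  conc = numeric()),
                         model, pbpk_preset("preterm"))
  expect_true(none$prior_only)
  expect_equal(none$value, exp(model$mu))
  # an overwhelmingly tight prior dominates informative data
  fx <- subject_fixture(gfr = 2.62)
  tight <- population_model(mean = 1.31, cv = 1e-4, sigma = 0.10)
  fit <- map_individual(fx$subject, fx$obs, tight, pbpk_preset("preterm"))
  expect_equal(fit$value, exp(tight$mu), tolerance = 1e-3)
})

test_that("ITS is exact for a homogeneous noise-free cohort", {
  fx <- lapply(1:3, function(i) subject_fixture(gfr = 1.5))
  subjects <- do.call(rbind, lapply(seq_along(fx), function(i)
    data.frame(id = i, group = "preterm", TBW = 1.73, GA = 34, PNA = 3,
               dose_per_kg = 6, infusion_h = 0.5, interval = 48)))
  obs <- do.call(rbind, lapply(seq_along(fx), function(i)
    cbind(id = i, fx[[i]]$obs, blq = FALSE)))
  ds <- tdm_dataset(subjects, obs)
  fit <- its_fit(ds, group = "preterm", estimate_sigma = FALSE,
                 init = population_model(mean = 1.31, cv = 0.4,
                                         sigma = 0.05))
  expect_true(fit$converged)
  expect_equal(exp(fit$model$mu), 1.5, tolerance = 1e-3)
})

test_that("ITS recovers a known population mean from synthetic TDM data", {
  ds <- generate_tdm(synthetic_study_spec(n_preterm = 31, n_term = 0,
                                          seed = 11))
  fit <- its_fit(ds$data, group = "preterm")
  expect_true(fit$converged)
  # truth: GFR arithmetic mean 1.31, CV 40%, 10% proportional error
  expect_lt(abs(fit$population_mean - 1.31) / 1.31, 0.15)
  expect_equal(fit$model$omega, sqrt(log(1 + 0.4^2)), tolerance = 0.5)
  # estimates match the generating per-subject truth reasonably
  merged <- merge(fit$individuals, ds$truth, by = "id")
  expect_gt(stats::cor(merged$estimate, merged$GFR), 0.8)
})

test_that("ITS is invariant to subject order and unit rescaling", {
  ds <- generate_tdm(synthetic_study_spec(n_preterm = 10, n_term = 0,
                                          seed = 3, n_missing = 0))
  fit <- its_fit(ds$data, group = "preterm")
  # subject order
  perm <- rev(seq_len(nrow(ds$data$subjects)))
  ds2 <- tdm_dataset(ds$data$subjects[perm, ], ds$data$obs)
  fit2 <- its_fit(ds2, group = "preterm")
  expect_equal(fit2$population_mean, fit$population_mean, tolerance = 1e-8)
  # rescaling dose and concentrations together (e.g. mg -> ug) changes
  # nothing under a proportional error model
  s3 <- ds$data$subjects; s3$dose_per_kg <- s3$dose_per_kg * 1000
  o3 <- ds$data$obs; o3$conc <- o3$conc * 1000
  fit3 <- its_fit(tdm_dataset(s3, o3, lloq = 300), group = "preterm")
  expect_equal(fit3$population_mean, fit$population_mean, tolerance = 1e-6)
})

test_that("ITS flags degenerate inputs instead of failing", {
  ds <- generate_tdm(synthetic_study_spec(n_preterm = 2, n_term = 0,
                                          seed = 5, n_missing = 0))
  one <- tdm_dataset(ds$data$subjects[1, , drop = FALSE],
                     ds$data$obs[ds$data$obs$id == 1, ])
  expect_warning(fit1 <- its_fit(one, group = "preterm"), "single subject")
  expect_equal(fit1$model$omega, population_model(mean = 1.31)$omega)
  # max_iter = 0 returns the initial model unconverged
  fit0 <- its_fit(ds$data, group = "preterm", max_iter = 0)
  expect_false(fit0$converged)
  expect_equal(exp(fit0$model$mu + fit0$model$omega^2 / 2), 1.31,
               tolerance = 1e-6)
  expect_error(its_fit(ds$data, group = "term"), "no subjects")
})

test_that("population-mean recovery error shrinks with cohort size", {
  err_at <- function(n, seeds) mean(vapply(seeds, function(s) {
    ds <- generate_tdm(synthetic_study_spec(n_preterm = n, n_term = 0,
                                            seed = s, n_missing = 0))
    fit <- its_fit(ds$data, group = "preterm")
    abs(fit$population_mean - 1.31) / 1.31
  }, 0))
  seeds <- c(21, 22, 23)
  e10 <- err_at(10, seeds)
  e100 <- err_at(100, seeds)
  # sampling noise scales ~ 1/sqrt(n); allow slack for the MC design
  expect_lt(e100, e10 + 0.05)
  expect_lt(e100, 0.10)
})
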