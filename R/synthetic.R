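#' Synthetic TDM study specification
#'
#' Describes a virtual neonatal gentamicin TDM study with the demographic
#' and sampling structure of a routine 2 h / 24 h monitoring design:
#' subjects per subgroup, demographic distributions (truncated normals
#' matched to reference mean, SD and min-max per subgroup), the dose
#' policy, the sampling times, the proportional residual error, the assay
#' LLOQ and a missingness count.
#'
#' Default demographics (mean, SD, min, max):
#' preterm (n 31) -- GA 33.7, 1.56, 32, 37 weeks; PNA 3.03, 1.02, 2, 7
#' days; TBW 1.96, 0.41, 1.16, 3.00 kg; dose 5.74, 0.80, 4.01, 6.88 mg/kg.
#' term (n 16) -- GA 38.9, 0.25, 38, 39; PNA 2.94, 0.85, 2, 5; TBW 3.09,
#' 0.23, 2.29, 3.62; dose 6.64, 0.22, 6.21, 6.99.
#'
#' @param n_preterm,n_term Subjects per subgroup (defaults 31 and 16).
#' @param dose_policy `"fixed"` (every subject receives `dose_fixed`
#'   mg/kg, the protocol's initial dose) or `"sampled"` (per-subject doses
#'   drawn from the demographic dose distribution).
#' @param dose_fixed Fixed dose, mg/kg (default 6).
#' @param sampling_times Nominal sampling times, h (default `c(2, 24)`).
#' @param residual_cv Proportional residual error SD (default 0.10).
#' @param lloq Assay lower limit of quantification, mg/L (default 0.3).
#' @param n_missing Number of samples removed at random across the study
#'   (default 3, emulating subjects contributing a single sample).
#' @param seed RNG seed.
#' @return An object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(n_preterm = 31L, n_term = 16L,
                                 dose_policy = c("fixed", "sampled"),
                                 dose_fixed = 6, sampling_times = c(2, 24),
                                 residual_cv = 0.10, lloq = 0.3,
                                 n_missing = 3L, seed = 1L) {
  dose_policy <- match.arg(dose_policy)
  if (n_preterm < 0 || n_term < 0 || n_preterm + n_term < 1)
    stop("at least one subject is required")
  if (residual_cv < 0) stop("residual_cv must be non-negative")
  demo <- list(
    preterm = list(GA = c(33.7, 1.56, 32, 37), PNA = c(3.03, 1.02, 2, 7),
                   TBW = c(1.96, 0.41, 1.16, 3.00),
                   dose = c(5.74, 0.80, 4.01, 6.88), interval = 48),
    term = list(GA = c(38.9, 0.25, 38, 39), PNA = c(2.94, 0.85, 2, 5),
                TBW = c(3.09, 0.23, 2.29, 3.62),
                dose = c(6.64, 0.22, 6.21, 6.99), interval = 36))
  structure(list(n = c(preterm = as.integer(n_preterm),
                       term = as.integer(n_term)),
                 demographics = demo, dose_policy = dose_policy,
                 dose_fixed = dose_fixed, sampling_times = sampling_times,
                 residual_cv = residual_cv, lloq = lloq,
                 n_missing = as.integer(n_missing),
                 seed = as.integer(seed)),
            class = "synthetic_study_spec")
}

# inverse-CDF truncated normal draw
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic TDM dataset
#'
#' Samples demographics from truncated normals, samples each subject's
#' physiological parameters (GFR, cardiac output, kidney flow log-normal
#' with the population CVs; distribution volume per the population spec's
#' policy; body weight taken from the demographics), simulates the true
#' concentration profile with the PBPK model, records concentrations at
#' the nominal sampling times with multiplicative proportional error,
#' censors values below the LLOQ, and removes `n_missing` samples at
#' random. Fully reproducible from the spec's seed.
#'
#' @param spec A [synthetic_study_spec()].
#' @param cv_map,vd_policy Passed to [population_spec()] for the
#'   physiological variability.
#' @param mode Structural model mode (default `"mass_conserving"`).
#' @return List with `data` (a [tdm_dataset()]) and `truth` (the
#'   generating per-subject parameters and noise-free concentrations, for
#'   recovery experiments).
#' @examples
#' ds <- generate_tdm(synthetic_study_spec(n_preterm = 4, n_term = 2,
#'                                         seed = 9))
#' ds$data
#' @export
generate_tdm <- function(spec, cv_map = c(TBW = 0.20, Qk = 0.20,
                                          CO = 0.24, GFR = 0.40),
                         vd_policy = "fixed", mode = "mass_conserving") {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  withr::with_seed(spec$seed, {
    subjects <- NULL; obs <- NULL; truth <- NULL
    next_id <- 1L
    for (grp in names(spec$n)) {
      ng <- spec$n[[grp]]
      if (ng == 0) next
      d <- spec$demographics[[grp]]
      draw <- function(v) rtruncnorm(ng, v[1], v[2], v[3], v[4])
      GA <- draw(d$GA); PNA <- draw(d$PNA); TBW <- draw(d$TBW)
      dose <- if (spec$dose_policy == "fixed")
        rep(spec$dose_fixed, ng) else draw(d$dose)
      # physiological parameters: TBW comes from the demographics, the
      # remaining varied parameters from the subpopulation distributions
      pop_cv <- cv_map[setdiff(names(cv_map), "TBW")]
      base <- pbpk_preset(grp)
      if (identical(vd_policy, "sampled"))
        pop_cv <- c(pop_cv,
                    Vd = switch(grp, preterm = 0.16 / 0.52,
                                term = 0.14 / 0.46))
      phys <- vapply(names(pop_cv), function(nm) {
        lm <- lognormal_moments(base[[nm]], pop_cv[[nm]])
        stats::rlnorm(ng, lm$mu, lm$sigma)
      }, numeric(ng))
      phys <- matrix(phys, nrow = ng,
                     dimnames = list(NULL, names(pop_cv)))
      ids <- next_id:(next_id + ng - 1L)
      next_id <- next_id + ng
      subjects <- rbind(subjects, data.frame(
        id = ids, group = grp, TBW = TBW, GA = GA, PNA = PNA,
        dose_per_kg = dose, infusion_h = 0.5, interval = d$interval))
      for (i in seq_len(ng)) {
        ov <- as.list(phys[i, ])
        ov$TBW <- TBW[i]
        p <- do.call(pbpk_parameters,
                     utils::modifyList(unclass(base), ov))
        s <- list(TBW = TBW[i], dose_per_kg = dose[i], infusion_h = 0.5,
                  interval = d$interval)
        true_conc <- predict_subject(p$GFR, "GFR", s, spec$sampling_times,
                                     p, mode = mode)
        noisy <- true_conc * (1 + spec$residual_cv *
                                stats::rnorm(length(true_conc)))
        noisy <- pmax(noisy, 0)
        blq <- noisy < spec$lloq
        obs <- rbind(obs, data.frame(
          id = ids[i], time = spec$sampling_times,
          conc = ifelse(blq, NA_real_, noisy), blq = blq))
        truth <- rbind(truth, data.frame(
          id = ids[i], group = grp, as.list(phys[i, , drop = TRUE]),
          TBW = TBW[i],
          t(stats::setNames(true_conc,
                            paste0("true_C", spec$sampling_times, "h")))))
      }
    }
    if (spec$n_missing > 0) {
      drop <- sample(nrow(obs), min(spec$n_missing, nrow(obs) - 1))
      obs <- obs[-drop, , drop = FALSE]
    }
    list(data = tdm_dataset(subjects, obs, lloq = spec$lloq),
         truth = truth)
  })
}

#' Demographic and exposure summary of a TDM dataset
#'
#' Per subgroup: subject count, mean, SD, min and max of gestational age,
#' postnatal age, body weight and dose, plus the concentration summary at
#' each nominal sampling time.
#'
#' @param tdm A [tdm_dataset()] (or a [generate_tdm()] result).
#' @return Data.frame, one row per subgroup x variable.
#' @export
summarize_cohort <- function(tdm) {
  if (is.list(tdm) && !inherits(tdm, "tdm_dataset") && !is.null(tdm$data))
    tdm <- tdm$data
  stopifnot(inherits(tdm, "tdm_dataset"))
  if (nrow(tdm$subjects) == 0) stop("empty dataset")
  summ <- function(x, grp, var) data.frame(
    group = grp, variable = var, n = sum(!is.na(x)),
    mean = mean(x, na.rm = TRUE),
    sd = if (sum(!is.na(x)) > 1) stats::sd(x, na.rm = TRUE) else 0,
    min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE))
  out <- NULL
  for (grp in unique(tdm$subjects$group)) {
    s <- tdm$subjects[tdm$subjects$group == grp, ]
    for (v in c("GA", "PNA", "TBW", "dose_per_kg"))
      if (v %in% names(s) && !all(is.na(s[[v]])))
        out <- rbind(out, summ(s[[v]], grp, v))
    o <- tdm$obs[tdm$obs$id %in% s$id & !tdm$obs$blq, ]
    for (tt in sort(unique(o$time)))
      out <- rbind(out, summ(o$conc[o$time == tt], grp,
                             sprintf("conc_%gh", tt)))
  }
  out
}
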