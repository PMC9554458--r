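#' Prediction error in percent
#'
#' `PE = (PRED - OBS) / OBS * 100`.
#'
#' @param pred Predicted value(s).
#' @param obs Observed value(s), non-zero.
#' @return Percent prediction error, vectorized.
#' @examples
#' prediction_error(17.4, 17.7) # -1.695
#' @export
prediction_error <- function(pred, obs) {
  if (any(obs == 0)) stop("OBS must be non-zero")
  (pred - obs) / obs * 100
}

#' Prediction/observation pair set
#'
#' Matched PRED/OBS records for predictive-performance evaluation,
#' optionally carrying the given and standard dose for dose normalization.
#'
#' @param pred,obs Positive numeric vectors of equal length.
#' @param subject_id Optional ids.
#' @param endpoint Optional endpoint labels (e.g. `"C2h"`, `"C24h"`,
#'   `"CL"`).
#' @param dose_given,dose_standard Optional per-record doses (mg/kg) for
#'   [dose_normalize()].
#' @return An object of class `pred_obs_set` (data.frame).
#' @export
pred_obs_set <- function(pred, obs, subject_id = seq_along(pred),
                         endpoint = "endpoint", dose_given = NA_real_,
                         dose_standard = NA_real_) {
  if (length(pred) != length(obs)) stop("pred and obs must be paired 1:1")
  if (length(pred) < 1) stop("at least one pair is required")
  df <- data.frame(subject_id = subject_id, endpoint = endpoint,
                   pred = pred, obs = obs, dose_given = dose_given,
                   dose_standard = dose_standard)
  structure(df, class = c("pred_obs_set", "data.frame"))
}

#' Bias and precision fold-error metrics
#'
#' Per endpoint: mean prediction error `MPE` (percent), average fold error
#' `AFE = 10^mean(log10(PRED/OBS))` (geometric bias) and absolute average
#' fold error `AAFE = 10^mean(|log10(PRED/OBS)|)` (precision). Predictive
#' performance is flagged acceptable when AFE and AAFE lie within the
#' 0.5- to 2-fold band.
#'
#' @param pairs A [pred_obs_set()] with strictly positive `pred` and
#'   `obs`.
#' @return An object of class `validation_report`: data.frame with one row
#'   per endpoint (`endpoint`, `n`, `mpe_percent`, `afe`, `aafe`,
#'   `acceptable`).
#' @examples
#' fold_error_metrics(pred_obs_set(c(2, 0.5), c(1, 1))) # AFE 1, AAFE 2
#' @export
fold_error_metrics <- function(pairs) {
  stopifnot(inherits(pairs, "pred_obs_set"))
  if (any(pairs$pred <= 0) || any(pairs$obs <= 0))
    stop("fold-error metrics require strictly positive PRED and OBS")
  out <- do.call(rbind, lapply(split(pairs, pairs$endpoint), function(g) {
    lr <- log10(g$pred / g$obs)
    afe <- 10^mean(lr)
    aafe <- 10^mean(abs(lr))
    data.frame(endpoint = g$endpoint[1], n = nrow(g),
               mpe_percent = mean(prediction_error(g$pred, g$obs)),
               afe = afe, aafe = aafe,
               acceptable = afe >= 0.5 && afe <= 2 && aafe <= 2)
  }))
  rownames(out) <- NULL
  structure(out, class = c("validation_report", "data.frame"))
}

#' Dose-normalize an observed concentration
#'
#' Rescales a concentration measured after `dose_given` mg/kg to the
#' standard dose used in the simulations, `conc * dose_standard /
#' dose_given`. Valid because the model is linear in dose.
#'
#' @param conc Observed concentration(s), mg/L.
#' @param dose_given Administered dose, mg/kg (> 0).
#' @param dose_standard Standard dose, mg/kg (default 6).
#' @return Normalized concentration(s).
#' @examples
#' dose_normalize(17.7, 5.74, 6) # 18.50
#' @export
dose_normalize <- function(conc, dose_given, dose_standard = 6) {
  if (any(is.na(dose_given)) || any(dose_given <= 0))
    stop("dose_given must be a positive dose in mg/kg")
  conc * dose_standard / dose_given
}

#' Simulation-based visual predictive check
#'
#' Compares dose-normalized observations at nominal sampling times against
#' the empirical percentile bands of a simulated virtual cohort. Bands are
#' the 10/25/50/75/90th percentiles plus the 5th-95th (90% PI) and
#' 25th-75th (50% PI) envelopes, computed by linear interpolation between
#' order statistics. Coverage is the fraction of observations inside the
#' 90% PI at their nominal time; the model is flagged adequate when the
#' overall coverage is at least `adequacy`.
#'
#' @param observed Data.frame with columns `time` (nominal sampling time,
#'   h), `conc` (mg/L) and optionally `dose_given` (mg/kg) for dose
#'   normalization.
#' @param profiles Simulated cohort, list of [concentration_profile()]
#'   (>= 100 subjects).
#' @param times Nominal times at which bands are computed; defaults to the
#'   distinct observed times.
#' @param dose_standard Standard dose, mg/kg, used for normalization when
#'   `observed$dose_given` is present.
#' @param percentiles Percentiles to tabulate (default 10/25/50/75/90).
#' @param adequacy Minimum overall 90%-PI coverage considered adequate
#'   (default 0.8).
#' @return An object of class `vpc_result`: `$bands` (time x percentile
#'   table, including `p5` and `p95`), `$coverage` per time,
#'   `$coverage_overall`, `$adequate`.
#' @export
vpc <- function(observed, profiles, times = NULL, dose_standard = 6,
                percentiles = c(10, 25, 50, 75, 90), adequacy = 0.8) {
  if (is.null(observed) || nrow(observed) == 0) stop("no observations")
  if (length(profiles) < 100)
    stop("VPC requires a simulated cohort of at least 100 subjects")
  if (is.null(times)) times <- sort(unique(observed$time))
  conc <- observed$conc
  if (!is.null(observed$dose_given) && !all(is.na(observed$dose_given)))
    conc <- dose_normalize(conc, observed$dose_given, dose_standard)

  sim <- vapply(profiles, function(p)
    stats::approx(p$times, p$Cb, xout = times, rule = 2)$y,
    numeric(length(times)))
  sim <- matrix(sim, nrow = length(times))
  qs <- sort(unique(c(percentiles, 5, 95, 25, 75))) / 100
  bands <- t(apply(sim, 1, stats::quantile, probs = qs, names = FALSE))
  bands <- data.frame(time = times, bands)
  names(bands)[-1] <- paste0("p", qs * 100)

  lo <- stats::setNames(bands$p5, as.character(bands$time))
  hi <- stats::setNames(bands$p95, as.character(bands$time))
  key <- as.character(observed$time)
  if (!all(key %in% names(lo)))
    stop("observed times not mappable to the band times")
  inside <- conc >= lo[key] & conc <= hi[key]
  coverage <- tapply(inside, observed$time, mean)
  overall <- mean(inside)
  structure(list(bands = bands, coverage = coverage,
                 coverage_overall = overall,
                 adequate = overall >= adequacy, n_sim = length(profiles),
                 n_obs = nrow(observed)),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("VPC: %d simulated subjects, %d observations\n",
              x$n_sim, x$n_obs))
  cat(sprintf("  90%% PI coverage: overall %.3f (%s)\n", x$coverage_overall,
              if (x$adequate) "adequate" else "inadequate"))
  invisible(x)
}

#' Write VPC percentile bands as tidy CSV
#'
#' @param result A [vpc()] result.
#' @param path Output CSV path (columns `time`, `percentile`, `value`).
#' @return `path`, invisibly.
#' @export
write_vpc_csv <- function(result, path) {
  stopifnot(inherits(result, "vpc_result"))
  b <- result$bands
  long <- do.call(rbind, lapply(names(b)[-1], function(pc)
    data.frame(time = b$time, percentile = as.numeric(sub("^p", "", pc)),
               value = b[[pc]])))
  utils::write.csv(long[order(long$time, long$percentile), ], path,
                   row.names = FALSE)
  invisible(path)
}
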