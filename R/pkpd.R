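#' PK/PD target criteria for aminoglycoside dosing
#'
#' Efficacy: peak-to-MIC ratio `Cmax/MIC >= 8` and time above MIC
#' `T>MIC >= 60` percent of the dosing interval. Toxicity: trough
#' `Cmin >= 2` mg/L and peak `Cmax >= 25` mg/L. A regimen is classified
#' effective when the population PTA of every efficacy criterion is at
#' least `pta_effective` percent (default 90) and safe when the PTA of
#' every toxicity criterion is at most `pta_safe` percent (default 10);
#' both decision thresholds are inclusive.
#'
#' @param cmax_mic_ratio Efficacy peak/MIC ratio threshold (default 8).
#' @param t_above_mic_pct Efficacy time-above-MIC threshold, percent of the
#'   interval (default 60).
#' @param cmin_toxic Trough toxicity threshold, mg/L (default 2).
#' @param cmax_toxic Peak toxicity threshold, mg/L (default 25).
#' @param pta_effective,pta_safe PTA decision thresholds, percent.
#' @return An object of class `pkpd_criteria`.
#' @export
pkpd_criteria <- function(cmax_mic_ratio = 8, t_above_mic_pct = 60,
                          cmin_toxic = 2, cmax_toxic = 25,
                          pta_effective = 90, pta_safe = 10) {
  vals <- c(cmax_mic_ratio, t_above_mic_pct, cmin_toxic, cmax_toxic,
            pta_effective, pta_safe)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all criterion thresholds must be positive")
  structure(list(cmax_mic_ratio = cmax_mic_ratio,
                 t_above_mic_pct = t_above_mic_pct,
                 cmin_toxic = cmin_toxic, cmax_toxic = cmax_toxic,
                 pta_effective = pta_effective, pta_safe = pta_safe),
            class = "pkpd_criteria")
}

# linear-interpolation time spent above a threshold on [0, interval]
time_above <- function(times, conc, threshold, interval) {
  keep <- times <= interval + 1e-9
  t <- times[keep]; c <- conc[keep]
  if (length(t) < 2) stop("profile does not cover the evaluation interval")
  d <- c - threshold
  seg <- diff(t)
  a <- d[-length(d)]; b <- d[-1]
  frac <- ifelse(a >= 0 & b >= 0, 1,
          ifelse(a <= 0 & b <= 0, 0,
          ifelse(a > 0, a / (a - b), b / (b - a))))
  sum(seg * frac)
}

#' Per-subject PK/PD indices over one dosing interval
#'
#' `Cmax` is the maximum blood concentration on the evaluation interval
#' (for this model it occurs at the end of the infusion, which the
#' simulation grid contains exactly), `Cmin` the concentration at the end
#' of the interval, and `T>MIC` the percentage of the interval with blood
#' concentration above the MIC, with threshold crossings located by linear
#' interpolation between grid points.
#'
#' @param profile A [concentration_profile()] covering the interval.
#' @param interval Evaluation interval, h; defaults to the profile's
#'   regimen interval (first dosing interval).
#' @param mic Minimum inhibitory concentration, mg/L. A non-positive MIC
#'   is degenerate: `T>MIC` is defined as 100% and a warning is emitted.
#' @return Named list `Cmax`, `Cmin`, `t_above_mic` (percent), `interval`.
#' @examples
#' prof <- simulate_profile(pbpk_preset("preterm"), dosing_regimen(6, 48))
#' compute_indices(prof, mic = 1)
#' @export
compute_indices <- function(profile, interval = NULL, mic = 1) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (is.null(interval)) {
    if (is.null(profile$regimen))
      stop("interval must be given when the profile has no regimen")
    interval <- profile$regimen$interval
  }
  if (max(profile$times) < interval - 1e-9)
    stop("profile does not cover the evaluation interval")
  keep <- profile$times <= interval + 1e-9
  cb <- profile$Cb[keep]
  cmax <- max(cb)
  cmin <- stats::approx(profile$times, profile$Cb, xout = interval,
                        rule = 2)$y
  if (mic <= 0) {
    warning("non-positive MIC: T>MIC defined as 100%")
    t_pct <- 100
  } else {
    t_pct <- 100 * time_above(profile$times, profile$Cb, mic, interval) /
      interval
  }
  list(Cmax = cmax, Cmin = cmin, t_above_mic = t_pct, interval = interval)
}

# per-subject Cmax/Cmin table computed once; T>MIC recomputed per MIC
cohort_exposure <- function(profiles, interval = NULL) {
  stopifnot(length(profiles) >= 1)
  idx <- lapply(profiles, compute_indices, interval = interval, mic = 1)
  data.frame(Cmax = vapply(idx, `[[`, 0, "Cmax"),
             Cmin = vapply(idx, `[[`, 0, "Cmin"))
}

#' Probability of target attainment over a MIC grid
#'
#' For each MIC on the grid and each PK/PD criterion, the percentage of
#' cohort subjects attaining the criterion. The trough and peak toxicity
#' criteria are MIC-independent and reported once per subject set. All
#' criterion comparisons use `>=` as stated in the criteria object.
#'
#' @param profiles List of [concentration_profile()] objects, one per
#'   subject of the simulated cohort (same regimen).
#' @param criteria A [pkpd_criteria()].
#' @param mic_grid Increasing MIC grid, mg/L. Default `seq(0.05, 2, 0.05)`
#'   (no MIC above the 2 mg/L clinical breakpoint is considered).
#' @param interval Evaluation interval, h (default: the regimen interval).
#' @return An object of class `pta_result`: `$pta` data.frame with columns
#'   `mic`, `criterion`, `pta_percent`; `$toxicity` named vector of the two
#'   MIC-independent toxicity PTAs; `$n` cohort size.
#' @examples
#' coh <- sample_cohort(population_spec("preterm", n = 50, seed = 7))
#' prof <- simulate_cohort(coh, dosing_regimen(6, 48))
#' res <- pta(prof, mic_grid = c(0.5, 1, 2))
#' res$pta
#' @export
pta <- function(profiles, criteria = pkpd_criteria(),
                mic_grid = seq(0.05, 2, by = 0.05), interval = NULL) {
  stopifnot(inherits(criteria, "pkpd_criteria"))
  if (length(profiles) == 0) stop("empty cohort")
  if (is.unsorted(mic_grid, strictly = TRUE))
    stop("mic_grid must be strictly increasing")
  exp_tab <- cohort_exposure(profiles, interval)
  n <- nrow(exp_tab)
  iv <- if (is.null(interval)) profiles[[1]]$regimen$interval else interval
  tmat <- vapply(profiles, function(p)
    vapply(mic_grid, function(m)
      100 * time_above(p$times, p$Cb, m, iv) / iv, 0),
    numeric(length(mic_grid)))
  tmat <- matrix(tmat, nrow = length(mic_grid))
  rows <- do.call(rbind, lapply(seq_along(mic_grid), function(j) {
    data.frame(
      mic = mic_grid[j],
      criterion = c("cmax_mic", "t_above_mic"),
      pta_percent = c(
        100 * mean(exp_tab$Cmax / mic_grid[j] >= criteria$cmax_mic_ratio),
        100 * mean(tmat[j, ] >= criteria$t_above_mic_pct)))
  }))
  toxicity <- c(cmin = 100 * mean(exp_tab$Cmin >= criteria$cmin_toxic),
                cmax = 100 * mean(exp_tab$Cmax >= criteria$cmax_toxic))
  structure(list(pta = rows, toxicity = toxicity, n = n,
                 criteria = criteria, interval = iv,
                 regimen = profiles[[1]]$regimen),
            class = "pta_result")
}

#' @export
print.pta_result <- function(x, ...) {
  cat(sprintf("PTA over %d subjects, interval %g h\n", x$n, x$interval))
  ref <- x$pta[abs(x$pta$mic - 1) < 1e-9, ]
  if (nrow(ref)) {
    cat("  at MIC 1 mg/L: ")
    cat(paste(sprintf("%s %.1f%%", ref$criterion, ref$pta_percent),
              collapse = ", "), "\n")
  }
  cat(sprintf("  toxicity: Cmin %.1f%%, Cmax %.1f%%\n",
              x$toxicity[["cmin"]], x$toxicity[["cmax"]]))
  invisible(x)
}

#' Highest MIC still attaining a PTA threshold
#'
#' Scans the PTA curve of one efficacy criterion and returns the largest
#' grid MIC with PTA at or above the threshold. The curve should be
#' non-increasing in MIC; a non-monotone curve beyond Monte Carlo noise
#' triggers a warning and the last down-crossing is used.
#'
#' @param result A [pta()] result.
#' @param criterion `"cmax_mic"` or `"t_above_mic"`.
#' @param threshold PTA threshold, percent (default 90).
#' @return The breakpoint MIC in mg/L, or `NA` with attribute
#'   `none_found = TRUE` when no grid MIC attains the threshold.
#' @export
mic_breakpoint <- function(result, criterion = "cmax_mic", threshold = 90) {
  stopifnot(inherits(result, "pta_result"))
  cur <- result$pta[result$pta$criterion == criterion, ]
  if (!nrow(cur)) stop("unknown criterion: ", criterion)
  cur <- cur[order(cur$mic), ]
  mc_noise <- 4 * 100 / sqrt(result$n)
  if (any(diff(cur$pta_percent) > mc_noise))
    warning("PTA curve is non-monotone beyond Monte Carlo noise; ",
            "using the last down-crossing")
  ok <- cur$pta_percent >= threshold
  if (!any(ok)) return(structure(NA_real_, none_found = TRUE))
  cur$mic[max(which(ok))]
}

#' Classify a regimen as effective and/or safe
#'
#' Applies the population decision rules at a reference MIC: effective
#' when both efficacy PTAs are at or above the effective threshold
#' (inclusive), safe when both toxicity PTAs are at or below the safe
#' threshold (inclusive).
#'
#' @param result A [pta()] result.
#' @param criteria A [pkpd_criteria()]; defaults to the criteria stored in
#'   `result`.
#' @param mic Reference MIC on the grid, mg/L (default 1).
#' @return List with per-criterion verdicts, overall `effective` and
#'   `safe` logicals, and the underlying PTA values.
#' @export
classify_regimen <- function(result, criteria = NULL, mic = 1) {
  stopifnot(inherits(result, "pta_result"))
  if (is.null(criteria)) criteria <- result$criteria
  at <- result$pta[abs(result$pta$mic - mic) < 1e-9, ]
  if (!nrow(at)) stop("MIC ", mic, " is not on the evaluated grid")
  eff <- stats::setNames(at$pta_percent, at$criterion)
  verdict <- list(
    cmax_mic = eff[["cmax_mic"]] >= criteria$pta_effective,
    t_above_mic = eff[["t_above_mic"]] >= criteria$pta_effective,
    cmin_toxic = result$toxicity[["cmin"]] <= criteria$pta_safe,
    cmax_toxic = result$toxicity[["cmax"]] <= criteria$pta_safe)
  list(mic = mic,
       pta = c(eff, cmin_toxic = result$toxicity[["cmin"]],
               cmax_toxic = result$toxicity[["cmax"]]),
       verdict = verdict,
       effective = verdict$cmax_mic && verdict$t_above_mic,
       safe = verdict$cmin_toxic && verdict$cmax_toxic)
}

#' Write PTA curves as tidy CSV
#'
#' @param result A [pta()] result.
#' @param path Output CSV path (columns `mic`, `criterion`,
#'   `pta_percent`).
#' @return `path`, invisibly.
#' @export
write_pta_csv <- function(result, path) {
  stopifnot(inherits(result, "pta_result"))
  utils::write.csv(result$pta, path, row.names = FALSE)
  invisible(path)
}
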