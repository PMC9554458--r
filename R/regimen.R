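#' Intravenous dosing regimen
#'
#' A periodic short-infusion schedule: `dose_per_kg` mg/kg infused over
#' `infusion_duration` hours at the start of each dosing interval, repeated
#' `n_doses` times. This is the rectangular pulse train driving the blood
#' equation.
#'
#' @param dose_per_kg Dose, mg/kg (> 0).
#' @param interval Dosing interval (pulse period), h.
#' @param n_doses Number of doses (>= 1).
#' @param infusion_duration Infusion length, h; default 0.5 (the 30-min IV
#'   infusion of the neonatal protocol).
#' @return An object of class `dosing_regimen`.
#' @examples
#' dosing_regimen(6, interval = 48)           # extended interval, preterm
#' dosing_regimen(4, interval = 24, n_doses = 3)
#' @export
dosing_regimen <- function(dose_per_kg, interval, n_doses = 1L,
                           infusion_duration = 0.5) {
  if (!is.numeric(dose_per_kg) || dose_per_kg <= 0)
    stop("dose_per_kg must be strictly positive")
  if (!is.numeric(interval) || interval <= 0)
    stop("interval must be strictly positive")
  if (!is.numeric(infusion_duration) || infusion_duration <= 0)
    stop("infusion_duration must be strictly positive")
  if (infusion_duration >= interval)
    stop("infusion_duration must be shorter than the dosing interval")
  n_doses <- as.integer(n_doses)
  if (is.na(n_doses) || n_doses < 1L) stop("n_doses must be >= 1")
  structure(list(dose_per_kg = dose_per_kg, interval = interval,
                 n_doses = n_doses, infusion_duration = infusion_duration),
            class = "dosing_regimen")
}

#' @export
print.dosing_regimen <- function(x, ...) {
  cat(sprintf("%g mg/kg q%gh x %d (%g-h infusion)\n",
              x$dose_per_kg, x$interval, x$n_doses, x$infusion_duration))
  invisible(x)
}

#' Instantaneous infusion rate of a regimen
#'
#' Piecewise-constant input rate in mg/h: `dose_per_kg * TBW /
#' infusion_duration` while `t` lies inside an infusion window
#' `[k * interval, k * interval + infusion_duration)` for `k < n_doses`,
#' else 0. The integral over one window equals the absolute dose in mg.
#'
#' @param t Time(s) since the first dose, h (vectorized).
#' @param regimen A [dosing_regimen()].
#' @param TBW Subject body weight, kg.
#' @return Infusion rate(s), mg/h.
#' @examples
#' r <- dosing_regimen(6, interval = 48)
#' infusion_rate(c(0.25, 1, 48.1), dosing_regimen(6, 48, n_doses = 2), 1.73)
#' @export
infusion_rate <- function(t, regimen, TBW) {
  stopifnot(inherits(regimen, "dosing_regimen"), TBW > 0)
  if (any(t < 0)) stop("t must be non-negative")
  k <- floor(t / regimen$interval)
  within_pulse <- (t - k * regimen$interval) < regimen$infusion_duration &
    k < regimen$n_doses
  rate <- regimen$dose_per_kg * TBW / regimen$infusion_duration
  ifelse(within_pulse, rate, 0)
}

# segment table (start, end, rate mg/h) tiling [0, n_doses * interval]
infusion_segments <- function(regimen, TBW) {
  rate <- regimen$dose_per_kg * TBW / regimen$infusion_duration
  k <- seq_len(regimen$n_doses) - 1L
  on_start <- k * regimen$interval
  on_end <- on_start + regimen$infusion_duration
  off_end <- (k + 1L) * regimen$interval
  data.frame(start = as.vector(rbind(on_start, on_end)),
             end = as.vector(rbind(on_end, off_end)),
             rate = as.vector(rbind(rep(rate, length(k)), rep(0, length(k)))))
}
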