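#' Physiological parameter set for one virtual subject
#'
#' Bundles every physiological quantity of the minimal neonatal gentamicin
#' PBPK model: a well-stirred heart chamber, a flow-limited kidney with
#' glomerular-filtration elimination (corrected for tubular reabsorption),
#' a lumped rest-of-tissues compartment, and the blood pool whose volume is
#' the gentamicin distribution volume.
#'
#' All organ volumes and flows are stored per kg of total body weight and
#' converted to absolute units (L, L/h) once, at model assembly.
#'
#' @param TBW Total body weight, kg.
#' @param CO Cardiac output, mL/min/kg; used as the heart flow rate.
#' @param GFR Glomerular filtration rate, mL/min/kg.
#' @param Vd Gentamicin distribution volume (blood-pool volume), L/kg.
#' @param Qk Kidney blood flow, mL/min/kg.
#' @param Qr Rest-of-tissues blood flow, mL/min/kg.
#' @param Vk Kidney volume, L/kg.
#' @param Vr Rest-of-tissues volume, L/kg.
#' @param Vh Heart chamber volume, L/kg. Never reported for neonates; the
#'   default 0.01 L/kg is inconsequential because the heart loop is
#'   net-neutral (see the sensitivity test in the package test suite).
#' @param Pk Kidney tissue:blood partition coefficient (dimensionless).
#' @param Pr Rest-of-tissues partition coefficient (dimensionless).
#' @param f_reab Fraction of filtered drug undergoing tubular reabsorption;
#'   default 0.21.
#' @return An object of class `pbpk_parameters` (named list).
#' @seealso [pbpk_preset()] for the preterm/term literature values.
#' @examples
#' p <- pbpk_parameters(TBW = 1.73, CO = 172, GFR = 1.31, Vd = 0.52)
#' renal_elimination_flow(p$TBW, p$GFR)
#' @export
pbpk_parameters <- function(TBW, CO, GFR, Vd,
                            Qk = 9.35, Qr = 217,
                            Vk = 0.03, Vr = 0.87, Vh = 0.01,
                            Pk = 10, Pr = 1, f_reab = 0.21) {
  p <- list(TBW = TBW, CO = CO, GFR = GFR, Vd = Vd, Qk = Qk, Qr = Qr,
            Vk = Vk, Vr = Vr, Vh = Vh, Pk = Pk, Pr = Pr, f_reab = f_reab)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite numeric value")
  }
  strict_pos <- setdiff(names(p), c("Vh", "f_reab", "GFR"))
  for (nm in strict_pos) if (p[[nm]] <= 0)
    stop("parameter '", nm, "' must be strictly positive, got ", p[[nm]])
  if (p$GFR < 0) stop("GFR must be non-negative")
  if (p$Vh < 0) stop("Vh must be non-negative")
  if (p$f_reab < 0 || p$f_reab >= 1)
    stop("f_reab must lie in [0, 1), got ", p$f_reab)
  structure(p, class = "pbpk_parameters")
}

#' Literature parameter presets for neonatal subpopulations
#'
#' Mean physiological values for preterm (gestational age 32-37 weeks) and
#' term (38-39 weeks) neonates younger than one week: body weight 1.73 /
#' 3.56 kg, cardiac output 172 mL/min/kg (both groups), GFR 1.31 / 1.72
#' mL/min/kg and gentamicin distribution volume 0.52 / 0.46 L/kg. Shared
#' organ constants: kidney volume 0.03 and rest-of-tissues volume 0.87,
#' kidney flow 9.35 and rest flow 217 mL/min/kg, partition coefficients 10
#' (kidney) and 1 (rest).
#'
#' The source table prints the organ volumes with an ambiguous unit. The
#' default reading (`volume_units = "L_per_kg"`) treats them as fractional
#' volumes in L per kg body weight; `volume_units = "mL"` treats them as
#' absolute millilitres, which makes the tissues kinetically negligible and
#' collapses the model to one-compartment behaviour in the blood pool. Both
#' readings are physiologically imperfect; see the package vignette.
#'
#' @param population `"preterm"` or `"term"`.
#' @param volume_units `"L_per_kg"` (default) or `"mL"` for the kidney and
#'   rest-of-tissues volumes.
#' @param ... Overrides passed on to [pbpk_parameters()].
#' @return A `pbpk_parameters` object.
#' @examples
#' pbpk_preset("preterm")
#' pbpk_preset("term", GFR = 1.324) # optimized GFR instead of literature
#' @export
pbpk_preset <- function(population = c("preterm", "term"),
                        volume_units = c("L_per_kg", "mL"), ...) {
  population <- match.arg(population)
  volume_units <- match.arg(volume_units)
  base <- switch(population,
    preterm = list(TBW = 1.73, CO = 172, GFR = 1.31, Vd = 0.52),
    term    = list(TBW = 3.56, CO = 172, GFR = 1.72, Vd = 0.46))
  args <- utils::modifyList(base, list(...))
  if (volume_units == "mL" && !any(c("Vk", "Vr") %in% names(list(...)))) {
    # absolute mL reading: convert to L and express per kg of this subject
    args$Vk <- ml_to_l(0.03) / args$TBW
    args$Vr <- ml_to_l(0.87) / args$TBW
  }
  do.call(pbpk_parameters, args)
}

#' @export
print.pbpk_parameters <- function(x, ...) {
  cat("Minimal PBPK parameter set (per-kg values)\n")
  cat(sprintf("  TBW %.3g kg | CO %.4g, GFR %.4g, Qk %.4g, Qr %.4g mL/min/kg\n",
              x$TBW, x$CO, x$GFR, x$Qk, x$Qr))
  cat(sprintf("  Vd %.3g, Vk %.3g, Vr %.3g, Vh %.3g L/kg | Pk %.3g, Pr %.3g | f_reab %.3g\n",
              x$Vd, x$Vk, x$Vr, x$Vh, x$Pk, x$Pr, x$f_reab))
  invisible(x)
}

#' Renal elimination flow from glomerular filtration
#'
#' The elimination flow driving drug loss from the kidney compartment:
#' `TBW * GFR * (1 - f_reab)` in mL/min. For gentamicin 21% of the filtered
#' drug is reabsorbed in the tubule and tubular secretion is negligible, so
#' the default correction factor is 0.79.
#'
#' @param TBW Total body weight, kg (> 0).
#' @param GFR Glomerular filtration rate, mL/min/kg (>= 0).
#' @param f_reab Tubular reabsorption fraction in `[0, 1)`.
#' @param units `"mL_min"` (default) or `"L_h"` for the systemic-clearance
#'   reporting convention.
#' @return Elimination flow, scalar.
#' @examples
#' renal_elimination_flow(1.73, 1.31)              # 1.79 mL/min
#' renal_elimination_flow(1.73, 1.31, units = "L_h") # 0.107 L/h
#' @export
renal_elimination_flow <- function(TBW, GFR, f_reab = 0.21,
                                   units = c("mL_min", "L_h")) {
  units <- match.arg(units)
  if (!is.numeric(TBW) || any(TBW <= 0)) stop("TBW must be strictly positive")
  if (!is.numeric(GFR) || any(GFR < 0)) stop("GFR must be non-negative")
  if (any(f_reab < 0 | f_reab >= 1)) stop("f_reab must lie in [0, 1)")
  q <- TBW * GFR * (1 - f_reab)
  if (units == "L_h") ml_min_to_l_h(q) else q
}

#' Closed-form whole-body clearance of the flow-limited model
#'
#' At steady state the kidney mass balance gives emergent venous
#' concentration `Ck/Pk = Qk Cb / (Qk + Qe)`, so systemic clearance is the
#' flow-limited extraction `Qe Qk / (Qk + Qe)`. Used as an independent
#' closed-form cross-check of the ODE solution (dose = CL x AUC for this
#' linear system).
#'
#' @param params A [pbpk_parameters()] object.
#' @param units `"L_h"` (default) or `"mL_min"`.
#' @return Systemic clearance, scalar.
#' @export
flow_limited_clearance <- function(params, units = c("L_h", "mL_min")) {
  units <- match.arg(units)
  stopifnot(inherits(params, "pbpk_parameters"))
  qe <- renal_elimination_flow(params$TBW, params$GFR, params$f_reab)
  qk <- params$Qk * params$TBW # mL/min
  cl <- qe * qk / (qk + qe)
  if (units == "L_h") ml_min_to_l_h(cl) else cl
}

# absolute-unit parameter assembly (mg, L, h); done once before integration
as_absolute <- function(params, renormalize_flows = FALSE) {
  stopifnot(inherits(params, "pbpk_parameters"))
  p <- params
  qr <- if (renormalize_flows) p$CO - p$Qk else p$Qr
  if (qr <= 0) stop("renormalized rest-tissue flow CO - Qk must be positive")
  list(
    Vh = p$Vh * p$TBW, Vk = p$Vk * p$TBW, Vr = p$Vr * p$TBW, Vd = p$Vd * p$TBW,
    Qh = ml_min_to_l_h(p$CO * p$TBW),
    Qk = ml_min_to_l_h(p$Qk * p$TBW),
    Qr = ml_min_to_l_h(qr * p$TBW),
    Qe = ml_min_to_l_h(renal_elimination_flow(p$TBW, p$GFR, p$f_reab)),
    Pk = p$Pk, Pr = p$Pr)
}
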