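#' Unit conversion helpers
#'
#' Pure converters between the clinical reporting units (mL/min, mL/min/kg)
#' and the internal simulation units (mg, L, h). All model assembly happens
#' once, in these units, before any integration.
#'
#' @param x Numeric vector of values to convert.
#' @return Numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
ml_min_to_l_h <- function(x) x * 60 / 1000

#' @rdname units
#' @export
l_h_to_ml_min <- function(x) x * 1000 / 60

#' @rdname units
#' @export
ml_to_l <- function(x) x / 1000
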