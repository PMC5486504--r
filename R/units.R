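#' Unit conversions
#'
#' The user-facing interface works in clinical units (mm, ml/min, bpm, Pa);
#' the solver works in SI. All conversions are centralized here.
#'
#' @param x numeric value(s) to convert.
#' @return Converted numeric value(s).
#' @name units
#' @keywords internal
NULL

#' @rdname units
mm_to_m <- function(x) x * 1e-3

#' @rdname units
m_to_mm <- function(x) x * 1e3

#' @rdname units
mlmin_to_m3s <- function(x) x * 1e-6 / 60

#' @rdname units
bpm_to_hz <- function(x) x / 60

`%||%` <- function(a, b) if (is.null(a)) b else a
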