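# Entrapment-efficiency and UV-calibration arithmetic.

#' Entrapment efficiency
#'
#' `EE% = (D_T - D_U) / D_T * 100`: the percentage of the total drug load
#' `D_T` retained by the carrier, where `D_U` is the unentrapped
#' (supernatant) drug found after ultracentrifugation. Scale-invariant in
#' the concentration units.
#'
#' @param d_total Total drug concentration `D_T` (mg/mL, `> 0`).
#' @param d_unentrapped Supernatant drug `D_U` (mg/mL, `0 <= D_U <= D_T`).
#' @return Entrapment efficiency in percent, in `[0, 100]`; vectorized.
#' @examples
#' entrapment_efficiency(3.75, 0.48) # 87.2
#' @export
entrapment_efficiency <- function(d_total, d_unentrapped) {
  stopifnot(all(d_total > 0))
  if (any(d_unentrapped < 0)) abort("supernatant drug D_U must be >= 0")
  if (any(d_unentrapped > d_total)) {
    abort("D_U > D_T: supernatant exceeds the total load (assay error)")
  }
  (d_total - d_unentrapped) / d_total * 100
}

#' Default UV calibration line for fluorescein
#'
#' Absorbance as a linear function of concentration,
#' `y = 0.88 x + 0.148` with `x` in µg/mL.
#'
#' @return A list with `slope` and `intercept`.
#' @export
default_calibration <- function() list(slope = 0.88, intercept = 0.148)

#' Absorbance from concentration
#'
#' @param x Concentration in µg/mL (`>= 0`).
#' @param calibration A list with `slope` (`> 0`) and `intercept`.
#' @return Predicted absorbance.
#' @export
absorbance_from_concentration <- function(x, calibration = default_calibration()) {
  stopifnot(all(x >= 0), calibration$slope > 0)
  calibration$slope * x + calibration$intercept
}

#' Concentration from absorbance
#'
#' Inverts the calibration line, `x = (y - intercept) / slope`. Readings
#' below the blank (`y < intercept`) are returned as 0 and flagged through
#' the logical `"below_blank"` attribute.
#'
#' @param y Absorbance reading(s).
#' @param calibration A list with `slope` (`> 0`) and `intercept`.
#' @return Concentration(s) in µg/mL with a `"below_blank"` attribute.
#' @export
concentration_from_absorbance <- function(y, calibration = default_calibration()) {
  stopifnot(calibration$slope > 0)
  below <- y < calibration$intercept
  if (any(below)) {
    warn(paste0(sum(below), " reading(s) below the blank; returned as 0"))
  }
  x <- pmax((y - calibration$intercept) / calibration$slope, 0)
  structure(x, below_blank = below)
}
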