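#' Unit conversions to CGS
#'
#' All internal computation uses CGS units (cm, g, s; stress in dyn/cm^2).
#' Configuration files may state pressures in kPa or mmHg and viscosities in
#' Pa.s; these helpers convert to CGS on the way in.
#'
#' @param x numeric value(s).
#' @return numeric value(s) in dyn/cm^2 (pressures) or g/(cm s) (viscosity).
#' @name units
NULL

#' @rdname units
#' @export
kpa_to_cgs <- function(x) x * 1e4

#' @rdname units
#' @export
mmhg_to_cgs <- function(x) x * 1333.22

#' @rdname units
#' @export
pa_to_cgs <- function(x) x * 10

#' @rdname units
#' @export
pas_to_cgs <- function(x) x * 10  # Pa.s -> poise = g/(cm s)

#' @rdname units
#' @export
cgs_to_pa <- function(x) x / 10
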