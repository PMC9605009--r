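#' Device luminance specification
#'
#' Photometric constants of the simulated display. The perimetric decibel
#' scale is attenuation relative to a 0-dB reference of 10,000 apostilbs
#' (Humphrey convention): `L(db) = reference_asb * 10^(-db / 10)`. The default
#' device ceiling of 125.73 cd/m^2 (395 asb) makes 14 dB the brightest
#' displayable test stimulus, and 40 dB (1 asb, 0.318 cd/m^2) is the top of
#' the test range; the adaptation background is 10 cd/m^2.
#'
#' @param reference_asb 0-dB reference luminance, apostilbs.
#' @param max_device_cdm2 Display ceiling, cd/m^2.
#' @param background_cdm2 Background luminance, cd/m^2.
#' @return A `luminance_spec` list.
#' @examples
#' spec <- luminance_spec()
#' db_to_asb(40, spec)  # 1 asb
#' @export
luminance_spec <- function(reference_asb = 10000, max_device_cdm2 = 125.73,
                           background_cdm2 = 10) {
  if (reference_asb <= 0 || max_device_cdm2 <= 0 || background_cdm2 <= 0) {
    abort("all luminances must be strictly positive")
  }
  if (max_device_cdm2 <= background_cdm2) {
    abort("max_device_cdm2 must exceed background_cdm2")
  }
  structure(
    list(reference_asb = reference_asb, max_device_cdm2 = max_device_cdm2,
         background_cdm2 = background_cdm2),
    class = "luminance_spec"
  )
}

#' Decibel / apostilb / candela conversions
#'
#' `db_to_asb()` and `luminance_to_db()` convert between perimetric decibels
#' (attenuation; higher dB = dimmer stimulus = better sensitivity) and
#' luminance in apostilbs. `asb_to_cdm2()` and `cdm2_to_asb()` convert between
#' apostilbs and cd/m^2 using the exact relation 1 asb = 1/pi cd/m^2.
#'
#' @param db Sensitivity/attenuation in dB.
#' @param asb Luminance in apostilbs.
#' @param cdm2 Luminance in cd/m^2.
#' @param spec A [luminance_spec()].
#' @return Numeric vector of converted values.
#' @examples
#' db_to_asb(40)            # 1 asb
#' asb_to_cdm2(395)         # 125.73 cd/m^2
#' luminance_to_db(395)     # ~14 dB
#' @export
db_to_asb <- function(db, spec = luminance_spec()) {
  stopifnot(is.finite(db))
  spec$reference_asb * 10^(-db / 10)
}

#' @rdname db_to_asb
#' @export
asb_to_cdm2 <- function(asb) {
  if (any(asb < 0)) abort("luminance cannot be negative")
  asb / pi
}

#' @rdname db_to_asb
#' @export
cdm2_to_asb <- function(cdm2) {
  if (any(cdm2 < 0)) abort("luminance cannot be negative")
  cdm2 * pi
}

#' @rdname db_to_asb
#' @export
luminance_to_db <- function(asb, spec = luminance_spec()) {
  if (any(asb <= 0)) abort("luminance must be strictly positive to convert to dB")
  10 * log10(spec$reference_asb / asb)
}

#' Clamp a requested intensity to the displayable gamut
#'
#' The device floor is the dB value of the display's maximum luminance
#' (~14.03 dB at the default 125.73 cd/m^2 ceiling); requests brighter than
#' that are clamped up to the floor. Requests dimmer than the 40 dB top of the
#' test range are clamped down to 40.
#'
#' @param db Requested intensity, dB.
#' @param spec A [luminance_spec()].
#' @return A tibble with columns `db` (displayable value) and `clamped`.
#' @examples
#' clamp_to_device(10)  # ~14.03, clamped
#' @export
clamp_to_device <- function(db, spec = luminance_spec()) {
  stopifnot(all(is.finite(db)))
  floor_db <- luminance_to_db(cdm2_to_asb(spec$max_device_cdm2), spec)
  out <- pmin(pmax(db, floor_db), 40)
  was_clamped <- out != db
  tibble::tibble(db = out, clamped = was_clamped)
}
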