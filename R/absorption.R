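#' Atmospheric conditions
#'
#' Bundle of the ambient conditions that control atmospheric sound
#' absorption. Defaults are the open-air reference conditions used
#' throughout the package for nacelle-height acoustics: 20 degrees C and
#' 60 percent relative humidity at standard pressure.
#'
#' @param temperature_c Air temperature in degrees Celsius.
#' @param relative_humidity_pct Relative humidity in percent (0, 100].
#' @param pressure_kpa Static air pressure in kilopascal.
#'
#' @return An object of class `atmosphere`.
#' @examples
#' atmosphere()
#' atmosphere(temperature_c = 10, relative_humidity_pct = 80)
#' @export
atmosphere <- function(temperature_c = 20, relative_humidity_pct = 60,
                       pressure_kpa = 101.325) {
  if (!is.finite(temperature_c) || temperature_c <= -50 || temperature_c >= 60)
    stop("`temperature_c` must be finite and in (-50, 60)", call. = FALSE)
  if (!is.finite(relative_humidity_pct) || relative_humidity_pct <= 0 ||
      relative_humidity_pct > 100)
    stop("`relative_humidity_pct` must be in (0, 100]", call. = FALSE)
  if (!is.finite(pressure_kpa) || pressure_kpa <= 0)
    stop("`pressure_kpa` must be positive", call. = FALSE)
  structure(
    list(temperature_c = temperature_c,
         relative_humidity_pct = relative_humidity_pct,
         pressure_kpa = pressure_kpa),
    class = "atmosphere")
}

#' @export
print.atmosphere <- function(x, ...) {
  cat(sprintf("<atmosphere> %.1f degC, %.0f%% RH, %.3f kPa\n",
              x$temperature_c, x$relative_humidity_pct, x$pressure_kpa))
  invisible(x)
}

#' Pure-tone atmospheric absorption coefficient (ISO 9613-1)
#'
#' Computes the pure-tone atmospheric absorption coefficient from the
#' analytic formulas of ISO 9613-1: classical (translational/rotational)
#' absorption plus the vibrational relaxation contributions of oxygen and
#' nitrogen, with relaxation frequencies driven by the water-vapour molar
#' concentration.
#'
#' @param freq_khz Frequency in kHz, in \[1, 200\]. Vectorised.
#' @param atm An [atmosphere()] object.
#'
#' @return Absorption coefficient alpha in dB per metre (same length as
#'   `freq_khz`).
#' @examples
#' atmospheric_absorption(20, atmosphere())
#' atmospheric_absorption(c(14, 26.4), atmosphere())
#' @export
atmospheric_absorption <- function(freq_khz, atm = atmosphere()) {
  if (!inherits(atm, "atmosphere")) stop("`atm` must be an atmosphere object",
                                         call. = FALSE)
  if (!is.numeric(freq_khz) || any(!is.finite(freq_khz)))
    stop("`freq_khz` must be finite numeric", call. = FALSE)
  if (any(freq_khz < 1 | freq_khz > 200))
    stop("`freq_khz` must lie in [1, 200] kHz", call. = FALSE)

  f <- freq_khz * 1000                       # Hz
  T_k <- atm$temperature_c + 273.15
  T0 <- 293.15                               # reference 20 degC
  T01 <- 273.16                              # triple point
  pr <- 101.325                              # reference pressure, kPa
  pa <- atm$pressure_kpa / pr                # relative pressure

  # water-vapour molar concentration (percent)
  psat_rel <- 10^(-6.8346 * (T01 / T_k)^1.261 + 4.6151)
  h <- atm$relative_humidity_pct * psat_rel / pa

  # relaxation frequencies of O2 and N2 (Hz)
  fr_o <- pa * (24 + 4.04e4 * h * (0.02 + h) / (0.391 + h))
  fr_n <- pa * (T_k / T0)^(-0.5) *
    (9 + 280 * h * exp(-4.170 * ((T_k / T0)^(-1 / 3) - 1)))

  f2 <- f^2
  8.686 * f2 * (
    1.84e-11 * (1 / pa) * sqrt(T_k / T0) +
      (T_k / T0)^(-2.5) * (
        0.01275 * exp(-2239.1 / T_k) / (fr_o + f2 / fr_o) +
          0.1068 * exp(-3352 / T_k) / (fr_n + f2 / fr_n)
      )
  )
}
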