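# Indoor / fully shaded WBGT after Bernard & Pourmoghani (1999): psychrometric
# wet bulb from (T, Td), natural wet bulb via the empirical low-air-speed
# correction, WBGT as Bernard's shaded weighting of Tnwb and Ta.

#' Indoor (shaded) WBGT, Bernard model
#'
#' Computes the wet bulb globe temperature for fully shaded (indoor)
#' conditions from dry-bulb temperature and dew point. The psychrometric wet
#' bulb is obtained from the iterative thermodynamic solver
#' ([thermodynamic_wet_bulb()]), converted to a natural wet bulb with
#' Bernard's wind-speed correction
#' \deqn{T_{nwb} = T_a - C(v)(T_a - T_{pwb}), \quad
#'       C(v) = 0.96 + 0.069 \log_{10} v \;(0.3 \le v < 3),}
#' with \eqn{T_{nwb} = T_{pwb}} for \eqn{v \ge 3} m/s, and combined as
#' \deqn{WBGT = 0.67\,T_{nwb} + 0.33\,T_a,} Bernard's shaded formulation
#' (with no radiant load the globe collapses to the air temperature).
#' The default wind speed of 1 m/s makes \eqn{C(v) = 0.96}.
#'
#' @param temperature Air temperature, degC.
#' @param dew_point Dew point, degC; must not exceed `temperature`.
#' @param wind Indoor air speed, m/s, at least 0.3 (below the empirical
#'   range of the correction an error is raised). Default 1.
#' @param pressure Barometric pressure, hPa.
#' @return A tibble with columns `natural_wet_bulb`, `globe_temperature`
#'   (equal to the air temperature under shade), `air_temperature`, `wbgt`.
#' @examples
#' bernard_indoor_wbgt(32, 26)
#' bernard_indoor_wbgt(30, 30)  # saturated: all components equal 30
#' @export
bernard_indoor_wbgt <- function(temperature, dew_point, wind = 1,
                                pressure = 1013) {
  n <- max(length(temperature), length(dew_point))
  t <- rep_len(temperature, n)
  td <- rep_len(dew_point, n)
  if (any(!is.na(t) & !is.na(td) & td > t + 1e-9)) {
    abort("`dew_point` must not exceed `temperature`.")
  }
  if (any(wind < 0.3)) {
    abort("`wind` must be at least 0.3 m/s for Bernard's indoor correction.")
  }
  td <- pmin(td, t)
  rh <- relative_humidity_from_vp(t, saturation_vapour_pressure(td))
  tpwb <- thermodynamic_wet_bulb(t, rh, pressure = pressure)
  cv <- ifelse(wind >= 3, 1, 0.96 + 0.069 * log10(wind))
  tnwb <- t - cv * (t - tpwb)
  tibble(
    natural_wet_bulb = tnwb,
    globe_temperature = t,
    air_temperature = t,
    wbgt = 0.67 * tnwb + 0.33 * t
  )
}
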