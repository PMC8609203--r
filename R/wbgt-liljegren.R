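# Outdoor WBGT after Liljegren et al. (2008): coupled energy balances of a
# standard 150 mm black globe and a wetted wick exposed to sun and wind,
# solved by damped fixed-point iteration. Constants are the source's
# published values.

LJ <- list(
  stefanb   = 5.6696e-8,   # Stefan-Boltzmann, W m-2 K-4
  cp        = 1003.5,      # specific heat of dry air, J kg-1 K-1
  m_air     = 28.97,       # g mol-1
  m_h2o     = 18.015,
  r_gas     = 8314.34,     # J kmol-1 K-1
  solar_const = 1367,      # W m-2
  diam_globe = 0.0508,     # m, standard 2-inch globe of the source
  emis_globe = 0.95,
  alb_globe  = 0.05,
  diam_wick  = 0.007,      # m
  len_wick   = 0.0254,     # m
  emis_wick  = 0.95,
  alb_wick   = 0.4,
  emis_sfc   = 0.999,
  alb_sfc    = 0.45
)
LJ$r_air <- LJ$r_gas / LJ$m_air
LJ$pr    <- LJ$cp / (LJ$cp + 1.25 * LJ$r_air)
LJ$ratio <- LJ$cp * LJ$m_air / LJ$m_h2o

# dynamic viscosity of air, kg m-1 s-1 (kinetic theory fit of the source)
lj_viscosity <- function(tk) {
  omega <- (tk / 97 - 2.9) / 0.4 * (-0.034) + 1.048
  2.6693e-6 * sqrt(LJ$m_air * tk) / (3.617^2 * omega)
}

lj_thermal_cond <- function(tk) (LJ$cp + 1.25 * LJ$r_air) * lj_viscosity(tk)

# diffusivity of water vapour in air, m2 s-1
lj_diffusivity <- function(tk, pres_hpa) {
  pcrit13  <- (36.4 * 218)^(1 / 3)
  tcrit512 <- (132 * 647.3)^(5 / 12)
  tcrit12  <- sqrt(132 * 647.3)
  mmix <- sqrt(1 / LJ$m_air + 1 / LJ$m_h2o)
  patm <- pres_hpa / 1013.25
  3.640e-4 * (tk / tcrit12)^2.334 * pcrit13 * tcrit512 * mmix / patm * 1e-4
}

# latent heat of vaporization, J kg-1
lj_h_evap <- function(tk) (313.15 - tk) / 30 * (-71100) + 2.4073e6

# atmospheric emissivity from vapour pressure (hPa)
lj_emis_atm <- function(vp_hpa) 0.575 * vp_hpa^(1 / 7)

# convective coefficient of a sphere, W m-2 K-1
lj_h_sphere <- function(diam, tk, pres_hpa, speed) {
  density <- pres_hpa * 100 / (LJ$r_air * tk)
  re <- pmax(speed, 0.1) * density * diam / lj_viscosity(tk)
  nu <- 2 + 0.6 * sqrt(re) * LJ$pr^(1 / 3)
  nu * lj_thermal_cond(tk) / diam
}

# convective coefficient of a (wick) cylinder, W m-2 K-1
lj_h_cylinder <- function(diam, tk, pres_hpa, speed) {
  a <- 0.56; b <- 0.281; c <- 0.4; d <- 0.44
  density <- pres_hpa * 100 / (LJ$r_air * tk)
  re <- pmax(speed, 0.1) * density * diam / lj_viscosity(tk)
  nu <- b * re^(1 - c) * LJ$pr^(1 - d)
  nu * lj_thermal_cond(tk) / diam
}

# Direct-beam fraction of global horizontal irradiance from the clearness
# index, and the irradiance cap at the top-of-atmosphere value. Returns the
# (possibly capped) solar and fdir.
lj_solar_parameters <- function(solar, cza) {
  toa <- LJ$solar_const * cza
  dark <- cza < cos(89.5 * pi / 180) | toa <= 0
  solar <- ifelse(dark, 0, pmin(solar, toa))
  s <- ifelse(dark | solar <= 0, 0, pmin(solar / toa, 0.85))
  fdir <- ifelse(s > 0, exp(3 - 1.34 * s - 1.65 / s), 0)
  fdir <- pmin(pmax(fdir, 0), 0.9)
  list(solar = solar, fdir = fdir)
}

#' Outdoor WBGT, Liljegren model
#'
#' Iteratively solves the coupled energy balances of (i) a black globe
#' (short- and long-wave radiative gain versus convective loss) for the
#' globe temperature and (ii) a wetted wick (radiative and convective gain
#' versus evaporative loss) for the natural wet bulb, following Liljegren
#' et al. (2008), and combines them as
#' \deqn{WBGT = 0.7\,T_{nwb} + 0.2\,T_g + 0.1\,T_a.}
#'
#' When the sun is below the horizon (`zenith > 90`) the solar load is set
#' to zero rather than erroring, since loggers run continuously. When only
#' global horizontal irradiance is supplied, the direct-beam fraction is
#' estimated from the clearness index with the source's empirical
#' parameterization; pass `direct_fraction` to override.
#'
#' @param temperature Air temperature, degC.
#' @param dew_point Dew point, degC.
#' @param wind Wind speed, m/s, strictly positive.
#' @param solar Global horizontal irradiance, W/m2, non-negative.
#' @param zenith Solar zenith angle, degrees.
#' @param direct_fraction Optional direct-beam fraction in \eqn{[0, 1]};
#'   `NULL` (default) estimates it from the clearness index.
#' @param pressure Barometric pressure, hPa.
#' @param tol Fixed-point convergence tolerance, degC.
#' @param max_iter Iteration cap; non-convergence aborts with the offending
#'   inputs echoed.
#' @return A tibble with columns `natural_wet_bulb`, `globe_temperature`,
#'   `air_temperature`, `wbgt`.
#' @examples
#' # full sun, light wind vs strong wind: wind cools
#' liljegren_wbgt(34, 25, wind = 1, solar = 1000, zenith = 20)
#' liljegren_wbgt(34, 25, wind = 10, solar = 1000, zenith = 20)
#' @export
liljegren_wbgt <- function(temperature, dew_point, wind, solar, zenith = 0,
                           direct_fraction = NULL, pressure = 1013,
                           tol = 0.02, max_iter = 50L) {
  n <- max(length(temperature), length(dew_point), length(wind),
           length(solar), length(zenith))
  t   <- rep_len(temperature, n)
  td  <- rep_len(dew_point, n)
  spd <- rep_len(wind, n)
  sol <- rep_len(solar, n)
  zen <- rep_len(zenith, n)
  if (any(!is.na(spd) & spd <= 0)) abort("`wind` must be strictly positive.")
  if (any(!is.na(sol) & sol < 0)) abort("`solar` must be non-negative.")
  if (any(!is.na(td) & !is.na(t) & td > t + 1e-9)) {
    abort("`dew_point` must not exceed `temperature`.")
  }
  td <- pmin(td, t)

  # night rule: sun below horizon => no solar load
  night <- zen > 90
  sol[night] <- 0
  zen[night] <- 90
  cza <- cos(pmin(zen, 89.5) * pi / 180)

  sp <- lj_solar_parameters(sol, cza)
  sol <- sp$solar
  fdir <- if (is.null(direct_fraction)) sp$fdir else rep_len(direct_fraction, n)

  tair <- t + 273.15
  eair <- saturation_vapour_pressure(td)        # ambient vapour pressure, hPa
  emis_at <- lj_emis_atm(pmax(eair, 0.1))
  tsfc <- tair                                   # surface assumed at air temp

  # --- globe temperature -----------------------------------------------
  tg <- tair
  converged <- rep(FALSE, n)
  for (i in seq_len(max_iter)) {
    tref <- 0.5 * (tg + tair)
    h <- lj_h_sphere(LJ$diam_globe, tref, pressure, spd)
    rad <- 0.5 * (emis_at * tair^4 + LJ$emis_sfc * tsfc^4) -
      h / (LJ$stefanb * LJ$emis_globe) * (tg - tair) +
      sol / (2 * LJ$stefanb * LJ$emis_globe) * (1 - LJ$alb_globe) *
        (fdir * (1 / (2 * cza) - 1) + 1 + LJ$alb_sfc)
    tg_new <- pmax(rad, 1)^0.25
    converged <- abs(tg_new - tg) <= tol
    tg <- 0.9 * tg + 0.1 * tg_new
    if (all(converged | is.na(tg))) break
  }
  if (!all(converged | is.na(tg))) {
    j <- which(!converged)[1]
    abort(sprintf(
      "globe balance did not converge (T=%g, Td=%g, wind=%g, solar=%g, zenith=%g).",
      t[j], td[j], spd[j], sol[j], zen[j]))
  }

  # --- natural wet bulb -------------------------------------------------
  twb <- td + 273.15
  converged <- rep(FALSE, n)
  for (i in seq_len(max_iter)) {
    tref <- 0.5 * (twb + tair)
    h <- lj_h_cylinder(LJ$diam_wick, tref, pressure, spd)
    fatm <- LJ$stefanb * LJ$emis_wick *
      (0.5 * (emis_at * tair^4 + LJ$emis_sfc * tsfc^4) - twb^4) +
      (1 - LJ$alb_wick) * sol *
        ((1 - fdir) * (1 + 0.25 * LJ$diam_wick / LJ$len_wick) +
           fdir * (tan(zen * pi / 180) / pi + 0.25 * LJ$diam_wick / LJ$len_wick) +
           LJ$alb_sfc)
    ewick <- saturation_vapour_pressure(pmin(twb - 273.15, 60))
    density <- pressure * 100 / (LJ$r_air * tref)
    sc <- lj_viscosity(tref) / (density * lj_diffusivity(tref, pressure))
    twb_new <- tair -
      lj_h_evap(tref) / LJ$ratio * (ewick - eair) / (pressure - ewick) *
        (LJ$pr / sc)^0.56 + fatm / h
    converged <- abs(twb_new - twb) <= tol
    twb <- 0.9 * twb + 0.1 * twb_new
    if (all(converged | is.na(twb))) break
  }
  if (!all(converged | is.na(twb))) {
    j <- which(!converged)[1]
    abort(sprintf(
      "wick balance did not converge (T=%g, Td=%g, wind=%g, solar=%g, zenith=%g).",
      t[j], td[j], spd[j], sol[j], zen[j]))
  }

  tnwb <- twb - 273.15
  tg_c <- tg - 273.15
  tibble(
    natural_wet_bulb = tnwb,
    globe_temperature = tg_c,
    air_temperature = t,
    wbgt = 0.7 * tnwb + 0.2 * tg_c + 0.1 * t
  )
}
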