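# Psychrometric primitives: saturation vapour pressure, humidity conversions,
# the Stull (2011) closed-form wet bulb and an independent iterative
# thermodynamic wet-bulb solver used as its accuracy oracle.

# Magnus saturation vapour pressure coefficients (Alduchov & Eskridge 1996),
# hPa over liquid water; invertible in closed form, <0.1% error over 0-50 degC.
MAGNUS_A <- 6.1094
MAGNUS_B <- 17.625
MAGNUS_C <- 243.04

# Psychrometer coefficient of the wet-bulb balance, K^-1 (Assmann value).
PSYCHRO_GAMMA <- 6.66e-4

#' Saturation vapour pressure over liquid water
#'
#' Magnus-form saturation vapour pressure
#' \eqn{e_s(T) = 6.1094 \exp(17.625 T / (243.04 + T))} in hPa, with the
#' Alduchov-Eskridge coefficients. Strictly increasing in temperature and
#' invertible in closed form (see [dew_point()]).
#'
#' @param temperature Dry-bulb air temperature in degrees Celsius, in
#'   \eqn{[-40, 60]}.
#' @return Saturation vapour pressure in hPa.
#' @examples
#' saturation_vapour_pressure(0)   # ~6.11 hPa
#' saturation_vapour_pressure(30)
#' @export
saturation_vapour_pressure <- function(temperature) {
  check_numeric(temperature, "temperature")
  bad <- !is.na(temperature) & (temperature < -40 | temperature > 60)
  if (any(bad)) {
    abort(sprintf(
      "`temperature` must lie in [-40, 60] degC; got %s.",
      toString(utils::head(temperature[bad], 3))))
  }
  MAGNUS_A * exp(MAGNUS_B * temperature / (MAGNUS_C + temperature))
}

#' Vapour pressure from temperature and relative humidity
#'
#' @param temperature Dry-bulb temperature, degC.
#' @param relative_humidity Relative humidity in percent, in \eqn{(0, 100]}.
#' @return Vapour pressure in hPa,
#'   `relative_humidity/100 * saturation_vapour_pressure(temperature)`.
#' @export
vapour_pressure <- function(temperature, relative_humidity) {
  check_numeric(relative_humidity, "relative_humidity")
  bad <- !is.na(relative_humidity) &
    (relative_humidity <= 0 | relative_humidity > 100)
  if (any(bad)) {
    abort("`relative_humidity` must lie in (0, 100] percent.")
  }
  relative_humidity / 100 * saturation_vapour_pressure(temperature)
}

#' Relative humidity from temperature and vapour pressure
#'
#' Inverse of [vapour_pressure()], capped at 100%: settlement-level vapour
#' pressure homogenization can imply supersaturation at the coolest logger
#' of an hour, which is clipped to saturation.
#'
#' @param temperature Dry-bulb temperature, degC.
#' @param vapour_pressure Vapour pressure in hPa, strictly positive.
#' @return Relative humidity in percent, in \eqn{(0, 100]}.
#' @export
relative_humidity_from_vp <- function(temperature, vapour_pressure) {
  check_numeric(vapour_pressure, "vapour_pressure")
  if (any(!is.na(vapour_pressure) & vapour_pressure <= 0)) {
    abort("`vapour_pressure` must be strictly positive.")
  }
  pmin(100, 100 * vapour_pressure / saturation_vapour_pressure(temperature))
}

#' Dew point from vapour pressure
#'
#' Closed-form inverse of the Magnus saturation curve:
#' `dew_point(saturation_vapour_pressure(t)) == t`.
#'
#' @param vapour_pressure Vapour pressure in hPa, strictly positive.
#' @return Dew point temperature, degC.
#' @export
dew_point <- function(vapour_pressure) {
  check_numeric(vapour_pressure, "vapour_pressure")
  if (any(!is.na(vapour_pressure) & vapour_pressure <= 0)) {
    abort("`vapour_pressure` must be strictly positive.")
  }
  lg <- log(vapour_pressure / MAGNUS_A)
  MAGNUS_C * lg / (MAGNUS_B - lg)
}

#' Closed-form wet bulb temperature (Stull approximation)
#'
#' The Stull (2011) empirical fit for wet bulb temperature at standard
#' sea-level pressure:
#' \deqn{T_W = T \arctan(0.151977 \sqrt{RH + 8.313659}) + \arctan(T + RH)
#'   - \arctan(RH - 1.676331) + 0.00391838\, RH^{3/2} \arctan(0.023101\, RH)
#'   - 4.686035}
#' The fit is stated for air temperatures between -20 and 50 degC and
#' relative humidity between 5 and 99 percent. For RH above 99% the air is
#' treated as saturated and the wet bulb equals the dry bulb. Inputs outside
#' the validity rectangle are flagged (`NA`) or raise an error, per
#' `on_invalid`.
#'
#' @param temperature Dry-bulb temperature, degC.
#' @param relative_humidity Relative humidity, percent.
#' @param on_invalid `"flag"` (default) returns `NA` for inputs outside the
#'   validity rectangle; `"error"` aborts.
#' @return Wet bulb temperature, degC, never exceeding `temperature`.
#' @seealso [thermodynamic_wet_bulb()] for the independent iterative solver.
#' @examples
#' stull_wet_bulb(20, 50)    # 13.7 degC in the source's worked example
#' stull_wet_bulb(31, 99.5)  # saturated: returns 31
#' @export
stull_wet_bulb <- function(temperature, relative_humidity,
                           on_invalid = c("flag", "error")) {
  on_invalid <- match.arg(on_invalid)
  check_numeric(temperature, "temperature")
  check_numeric(relative_humidity, "relative_humidity")
  n <- max(length(temperature), length(relative_humidity))
  t <- rep_len(temperature, n)
  rh <- rep_len(relative_humidity, n)

  saturated <- !is.na(rh) & rh > 99
  invalid <- !is.na(t) & !is.na(rh) & !saturated &
    (t < -20 | t > 50 | rh < 5)
  if (any(invalid) && on_invalid == "error") {
    abort(sprintf(
      "%d input(s) outside the validity rectangle T in [-20,50], RH in [5,99].",
      sum(invalid)))
  }

  tw <- t * atan(0.151977 * sqrt(rh + 8.313659)) +
    atan(t + rh) - atan(rh - 1.676331) +
    0.00391838 * rh^1.5 * atan(0.023101 * rh) - 4.686035
  tw <- pmin(tw, t)
  tw[saturated] <- t[saturated]
  tw[invalid] <- NA_real_
  tw[is.na(t) | is.na(rh)] <- NA_real_
  tw
}

#' Thermodynamic (psychrometric) wet bulb temperature
#'
#' Independent iterative solver of the psychrometric balance
#' \deqn{e_s(T_w) - e = \gamma P (T - T_w)}
#' by bisection on the bracket \eqn{[T_d, T]}, with the Assmann psychrometer
#' coefficient \eqn{\gamma = 6.66 \times 10^{-4}\,\mathrm{K}^{-1}} by default.
#' Serves as the accuracy oracle for [stull_wet_bulb()]; the two share no
#' code beyond the saturation curve.
#'
#' @param temperature Dry-bulb temperature, degC.
#' @param relative_humidity Relative humidity, percent, in \eqn{(0, 100]}.
#' @param pressure Barometric pressure, hPa (default 1013, standard sea
#'   level; the study settlements lie 1-19 m above sea level).
#' @param gamma Psychrometer coefficient, K^-1.
#' @param tol Convergence tolerance on the bracket width, degC.
#' @param max_iter Iteration cap; exceeding it aborts with diagnostics.
#' @return Wet bulb temperature, degC, with
#'   `dew_point <= result <= temperature`.
#' @export
thermodynamic_wet_bulb <- function(temperature, relative_humidity,
                                   pressure = 1013, gamma = PSYCHRO_GAMMA,
                                   tol = 1e-3, max_iter = 100L) {
  check_numeric(temperature, "temperature")
  n <- max(length(temperature), length(relative_humidity))
  t <- rep_len(temperature, n)
  rh <- rep_len(relative_humidity, n)
  vp <- vapour_pressure(t, rh)

  lo <- dew_point(vp)
  hi <- t
  # Saturated air: the bracket is degenerate and the root is the dry bulb.
  done <- !is.na(lo) & !is.na(hi) & (hi - lo) <= tol
  iter <- 0L
  while (!all(done | is.na(lo))) {
    iter <- iter + 1L
    if (iter > max_iter) {
      abort(sprintf(
        "wet-bulb bisection failed to converge within %d iterations (e.g. T=%g, RH=%g).",
        max_iter, t[!done][1], rh[!done][1]))
    }
    mid <- (lo + hi) / 2
    resid <- saturation_vapour_pressure(mid) - vp - gamma * pressure * (t - mid)
    neg <- !done & resid < 0
    lo <- ifelse(neg, mid, lo)
    hi <- ifelse(!done & !neg, mid, hi)
    done <- done | is.na(lo) | (hi - lo) <= tol
  }
  (lo + hi) / 2
}

#' Construct a psychrometric state table
#'
#' Bundles dry-bulb temperature, relative humidity, vapour pressure and dew
#' point into one tibble, enforcing the pairwise identities between them.
#'
#' @inheritParams thermodynamic_wet_bulb
#' @return A tibble with columns `temperature`, `relative_humidity`,
#'   `vapour_pressure`, `dew_point`, `pressure`.
#' @export
psychro_state <- function(temperature, relative_humidity, pressure = 1013) {
  vp <- vapour_pressure(temperature, relative_humidity)
  tibble(
    temperature = temperature,
    relative_humidity = relative_humidity,
    vapour_pressure = vp,
    dew_point = dew_point(vp),
    pressure = pressure
  )
}

check_numeric <- function(x, name) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be numeric.", name))
  }
  invisible(x)
}
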