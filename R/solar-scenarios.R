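# Solar geometry and the wind/solar scenario machinery used to recompute
# outdoor WBGT under fixed radiation and wind combinations.

# Mean coordinates of the monitored settlements (Makassar, Indonesia).
STUDY_LATITUDE <- -5.13
STUDY_LONGITUDE <- 119.42
# Mid-study reference date for the fixed "midday" scenario zenith.
STUDY_REFERENCE_DATE <- as.Date("2019-03-01")

#' Solar zenith angle
#'
#' Low-precision solar ephemeris (Astronomical Almanac approximation, good
#' to a few hundredths of a degree over the study years): solar declination
#' and equation of time from the mean solar longitude and anomaly, then the
#' local hour angle from the timestamp and longitude.
#'
#' @param latitude Degrees north.
#' @param longitude Degrees east.
#' @param timestamp A `POSIXct` timestamp with an explicit timezone (the UTC
#'   offset must be known; a bare timestamp is an error).
#' @return Solar zenith angle in degrees, in \eqn{[0, 180]}; values above 90
#'   mean the sun is below the horizon.
#' @examples
#' noon <- as.POSIXct("2019-03-01 12:00:00", tz = "Etc/GMT-8")
#' solar_position(-5.13, 119.42, noon)  # near-overhead sun
#' @export
solar_position <- function(latitude, longitude, timestamp) {
  if (!inherits(timestamp, "POSIXct")) {
    abort("`timestamp` must be POSIXct with an explicit timezone.")
  }
  tzone <- attr(timestamp, "tzone")
  if (is.null(tzone) || identical(tzone, "")) {
    abort("`timestamp` must carry an explicit timezone so the UTC offset is known.")
  }
  # days (fractional) since J2000.0
  nd <- as.numeric(difftime(timestamp,
                            as.POSIXct("2000-01-01 12:00:00", tz = "UTC"),
                            units = "days"))
  deg2rad <- pi / 180
  L <- (280.460 + 0.9856474 * nd) %% 360          # mean longitude, deg
  g <- ((357.528 + 0.9856003 * nd) %% 360) * deg2rad  # mean anomaly, rad
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * deg2rad
  eps <- (23.439 - 4e-7 * nd) * deg2rad           # obliquity
  decl <- asin(sin(eps) * sin(lambda))
  # right ascension, same quadrant as lambda
  alpha <- atan2(cos(eps) * sin(lambda), cos(lambda))
  eqtime_deg <- L - alpha / deg2rad               # equation of time, degrees
  eqtime_deg <- ((eqtime_deg + 180) %% 360) - 180
  # true solar time in degrees from solar midnight
  utc_hours <- as.numeric(format(timestamp, "%H", tz = "UTC")) +
    as.numeric(format(timestamp, "%M", tz = "UTC")) / 60 +
    as.numeric(format(timestamp, "%S", tz = "UTC")) / 3600
  hour_angle <- (utc_hours * 15 + longitude + eqtime_deg - 180) * deg2rad
  lat <- latitude * deg2rad
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(hour_angle)
  acos(pmin(1, pmax(-1, cosz))) / deg2rad
}

#' Default wind/solar scenarios
#'
#' The four scenario combinations used to bracket outdoor daytime WBGT:
#' full shade with high wind (low stress), moderate sun and wind, high sun
#' with high wind, and high sun with low wind (high stress).
#'
#' @return A tibble with columns `label`, `solar` (W/m2, 0 for shade),
#'   `wind` (m/s), `shaded` (logical).
#' @export
default_scenarios <- function() {
  tibble(
    label = c("shade_wind10", "sun400_wind3", "sun1000_wind10", "sun1000_wind1"),
    solar = c(0, 400, 1000, 1000),
    wind = c(10, 3, 10, 1),
    shaded = c(TRUE, FALSE, FALSE, FALSE)
  )
}

#' Read scenario definitions from a JSON or YAML file
#'
#' The file holds a list of records with keys `label`, `solar`, `wind`,
#' `shaded` (format chosen by extension: `.json`, `.yaml`/`.yml`).
#'
#' @param path File path.
#' @return A scenario tibble as in [default_scenarios()].
#' @export
read_scenarios <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    yaml = ,
    yml = {
      y <- yaml::read_yaml(path)
      do.call(rbind.data.frame, lapply(y, as.data.frame))
    },
    abort(sprintf("unsupported scenario file extension '%s'.", ext))
  )
  sc <- as_tibble(raw)
  required <- c("label", "solar", "wind", "shaded")
  if (!all(required %in% names(sc))) {
    abort("scenario file must provide label, solar, wind, shaded.")
  }
  validate_scenarios(sc[required])
}

validate_scenarios <- function(scenarios) {
  if (any(scenarios$solar < 0)) abort("scenario `solar` must be >= 0.")
  if (any(scenarios$wind <= 0)) abort("scenario `wind` must be > 0.")
  scenarios
}

#' Recompute outdoor WBGT under fixed wind/solar scenarios
#'
#' For each scenario, recomputes WBGT for every supplied daytime outdoor
#' record using the scenario's constant wind and solar radiation and a fixed
#' midday solar zenith at the mean settlement coordinates. Shaded scenarios
#' route through the Bernard shaded model at the scenario wind speed;
#' sunlit scenarios use the Liljegren model.
#'
#' @param records A tibble of daytime outdoor thermal records with columns
#'   `adj_temperature_c` and `dew_point_c` (extra columns are carried along).
#' @param scenarios Scenario tibble, see [default_scenarios()].
#' @param latitude,longitude Coordinates for the scenario zenith; default
#'   the mean settlement location.
#' @param reference_date Date on which the midday zenith is evaluated
#'   (default mid-study, 2019-03-01).
#' @param pressure Barometric pressure, hPa.
#' @return The records replicated per scenario (long format), with columns
#'   `scenario` and `wbgt_c` appended.
#' @export
apply_scenarios <- function(records, scenarios = default_scenarios(),
                            latitude = STUDY_LATITUDE,
                            longitude = STUDY_LONGITUDE,
                            reference_date = STUDY_REFERENCE_DATE,
                            pressure = 1013) {
  scenarios <- validate_scenarios(scenarios)
  if (nrow(records) == 0) {
    warn("`records` is empty; returning an empty scenario table.")
    return(mutate(records, scenario = character(0), wbgt_c = numeric(0)))
  }
  noon <- as.POSIXct(paste(reference_date, "12:00:00"), tz = TZ_LOCAL)
  zenith <- solar_position(latitude, longitude, noon)
  out <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    wbgt <- if (sc$shaded) {
      bernard_indoor_wbgt(records$adj_temperature_c, records$dew_point_c,
                          wind = sc$wind, pressure = pressure)$wbgt
    } else {
      liljegren_wbgt(records$adj_temperature_c, records$dew_point_c,
                     wind = sc$wind, solar = sc$solar, zenith = zenith,
                     pressure = pressure)$wbgt
    }
    mutate(records, scenario = sc$label, wbgt_c = wbgt)
  })
  bind_rows(out)
}
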