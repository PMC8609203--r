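# Sensor pipeline: raw logger records -> analysis-ready thermal records.
# Stages: solar-inflation percentile adjustment, joint temperature/humidity
# validity filtering, house hourly means, settlement median vapour pressure,
# humidity/dew-point reconstruction, and TW/WBGT attachment.

LOGGER_COLUMNS <- c("logger_id", "site_id", "placement", "house_id",
                    "timestamp", "temperature_c", "rh_pct")

#' Read a logger CSV
#'
#' One record per row with header
#' `logger_id,site_id,placement,house_id,timestamp,temperature_c,rh_pct`
#' (ISO-8601 timestamps; an empty field is missing). Timestamps without an
#' explicit zone are taken as local civil time (UTC+8).
#'
#' @param path CSV file path.
#' @return A validated logger-record tibble.
#' @export
read_logger_csv <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      logger_id = readr::col_character(),
      site_id = readr::col_character(),
      placement = readr::col_character(),
      house_id = readr::col_character(),
      timestamp = readr::col_character(),
      temperature_c = readr::col_double(),
      rh_pct = readr::col_double()
    ),
    progress = FALSE
  )
  raw$timestamp <- parse_local_time(raw$timestamp)
  validate_logger_records(raw)
}

#' Write logger records to CSV
#'
#' @param records Logger-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_logger_csv <- function(records, path) {
  out <- records
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = TZ_LOCAL)
  readr::write_csv(out[LOGGER_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Validate a logger-record tibble
#'
#' Checks the column contract, that placements are `house`/`outdoor`, that
#' house loggers (temperature-only hardware) carry no humidity, and that
#' timestamps align to whole hours.
#'
#' @param records Logger-record tibble.
#' @return The records, invisibly usable in a pipe.
#' @export
validate_logger_records <- function(records) {
  missing_cols <- setdiff(LOGGER_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("logger records lack column(s): %s.",
                  toString(missing_cols)))
  }
  if (!all(records$placement %in% c("house", "outdoor"))) {
    abort("`placement` must be 'house' or 'outdoor'.")
  }
  if (any(records$placement == "house" & !is.na(records$rh_pct))) {
    abort("house loggers are temperature-only; `rh_pct` must be missing.")
  }
  if (any(as.numeric(records$timestamp) %% 3600 != 0)) {
    abort("timestamps must align to whole hours.")
  }
  as_tibble(records)
}

#' Percentile adjustment for solar-inflated temperatures
#'
#' Shielded loggers can still read high under direct sun. For each timepoint
#' within each group (by default a settlement x placement class), values
#' above the group's `quantile` (type-7 linear-interpolation quantile, the R
#' default) are set to that quantile; values at or below it are untouched.
#' Record count is conserved.
#'
#' @param records Logger-record tibble.
#' @param quantile Capping quantile as a fraction (default 0.95).
#' @param grouping `"settlement"` (default) pools loggers within a
#'   settlement and placement class; `"citywide"` pools across settlements
#'   (sensitivity mode).
#' @return A list with `records` (input plus `adj_temperature_c`, `capped`,
#'   and `adjust_flag` marking groups too small for a meaningful quantile)
#'   and `report` (per site/placement capping counts and magnitudes).
#' @export
percentile_adjust <- function(records, quantile = 0.95,
                              grouping = c("settlement", "citywide")) {
  grouping <- match.arg(grouping)
  if (quantile <= 0 || quantile >= 1) abort("`quantile` must be in (0, 1).")
  validate_logger_records(records)
  keys <- if (grouping == "settlement") {
    c("site_id", "placement", "timestamp")
  } else {
    c("placement", "timestamp")
  }
  out <- records |>
    group_by(across(all_of(keys))) |>
    mutate(
      .n_group = sum(!is.na(.data$temperature_c)),
      .cap = if (sum(!is.na(.data$temperature_c)) == 0) NA_real_ else
        stats::quantile(.data$temperature_c, .env$quantile,
                        na.rm = TRUE, names = FALSE, type = 7),
      adj_temperature_c = pmin(.data$temperature_c, .data$.cap),
      capped = !is.na(.data$temperature_c) & !is.na(.data$.cap) &
        .data$temperature_c > .data$.cap,
      adjust_flag = .data$.n_group < 2
    ) |>
    ungroup()
  if (any(out$adjust_flag)) {
    warn(sprintf(
      "%d record(s) sit in groups with fewer than 2 observations; passed through flagged.",
      sum(out$adjust_flag)))
  }
  report <- out |>
    group_by(.data$site_id, .data$placement) |>
    summarise(
      n_records = n(),
      n_capped = sum(.data$capped),
      total_excess = sum((.data$temperature_c - .data$adj_temperature_c)[.data$capped]),
      max_excess = if (any(.data$capped))
        max(.data$temperature_c - .data$adj_temperature_c) else 0,
      .groups = "drop"
    )
  out <- select(out, -".cap", -".n_group")
  list(records = out, report = report)
}

#' Hourly mean adjusted temperature per house
#'
#' Averages the adjusted temperatures of all loggers reporting for a house
#' in each hour (up to six: three hourly, three two-hourly, so the mean
#' denominator alternates). Hours with no observation are absent.
#'
#' @param records Adjusted house logger records (must carry
#'   `adj_temperature_c`).
#' @return A tibble with `site_id`, `unit_id` (the house), `placement`,
#'   `timestamp`, `adj_temperature_c`, `n_loggers`.
#' @export
house_hourly_mean <- function(records) {
  records <- filter(records, .data$placement == "house",
                    !is.na(.data$adj_temperature_c))
  records |>
    group_by(.data$site_id, unit_id = .data$house_id, .data$timestamp) |>
    summarise(
      placement = "house",
      adj_temperature_c = mean(.data$adj_temperature_c),
      n_loggers = n(),
      .groups = "drop"
    ) |>
    select("site_id", "unit_id", "placement", "timestamp",
           "adj_temperature_c", "n_loggers")
}

#' Settlement median vapour pressure series
#'
#' Vapour pressure of each RH-reporting outdoor logger (from its adjusted
#' temperature and reported RH), reduced to the per-settlement, per-hour
#' median (even counts take the midpoint of the two central values).
#'
#' @param records Adjusted outdoor logger records with `rh_pct`.
#' @return A tibble with `site_id`, `timestamp`, `vapour_pressure_hpa`,
#'   `n_loggers`.
#' @export
settlement_median_vp <- function(records) {
  records <- filter(records, .data$placement == "outdoor",
                    !is.na(.data$rh_pct), !is.na(.data$adj_temperature_c))
  records |>
    mutate(vp = vapour_pressure(.data$adj_temperature_c, .data$rh_pct)) |>
    group_by(.data$site_id, .data$timestamp) |>
    summarise(
      vapour_pressure_hpa = stats::median(.data$vp),
      n_loggers = n(),
      .groups = "drop"
    )
}

#' Reconstruct relative humidity and dew point from homogenized vapour pressure
#'
#' Applies the settlement-hour vapour pressure to a unit's own adjusted
#' temperature: RH is the (capped) saturation ratio, dew point the Magnus
#' inverse of the vapour pressure. Applied identically to houses and
#' outdoor loggers.
#'
#' @param adj_temperature Adjusted temperature, degC.
#' @param settlement_vp Settlement median vapour pressure, hPa.
#' @return A tibble with `relative_humidity_pct` and `dew_point_c`.
#' @export
reconstruct_humidity <- function(adj_temperature, settlement_vp) {
  tibble(
    relative_humidity_pct =
      relative_humidity_from_vp(adj_temperature, settlement_vp),
    dew_point_c = dew_point(settlement_vp)
  )
}

#' Joint temperature/humidity validity filter
#'
#' Only periods where a settlement has both temperature and humidity
#' coverage enter the analyses: a settlement-hour lacking either a
#' temperature record or an RH-bearing outdoor record is dropped for all
#' units of that settlement.
#'
#' @param records Logger-record tibble (raw or adjusted).
#' @return A list with `records` (filtered) and `report` (per-settlement
#'   input/output/dropped counts).
#' @export
joint_validity_filter <- function(records) {
  coverage <- records |>
    group_by(.data$site_id, .data$timestamp) |>
    summarise(
      has_temp = any(!is.na(.data$temperature_c)),
      has_rh = any(!is.na(.data$rh_pct)),
      .groups = "drop"
    ) |>
    mutate(valid = .data$has_temp & .data$has_rh)
  kept <- records |>
    inner_join(filter(coverage, .data$valid) |>
                 select("site_id", "timestamp"),
               by = c("site_id", "timestamp"))
  report <- records |>
    group_by(.data$site_id) |>
    summarise(n_in = n(), .groups = "drop") |>
    left_join(kept |>
                group_by(.data$site_id) |>
                summarise(n_out = n(), .groups = "drop"),
              by = "site_id") |>
    mutate(n_out = coalesce(.data$n_out, 0L),
           n_dropped = .data$n_in - .data$n_out)
  list(records = kept, report = report)
}

#' Attach wet bulb temperature and WBGT to processed records
#'
#' Takes unit-level records that already carry adjusted temperature,
#' settlement vapour pressure, reconstructed RH and dew point, and appends
#' the Stull wet bulb (`tw_c`; saturated records, RH > 99%, take the dry
#' bulb) and WBGT (`wbgt_c`): houses through the Bernard shaded model at
#' 1 m/s, outdoor units through the Liljegren model at the supplied wind and
#' solar radiation with a per-record solar zenith. Records whose inputs
#' fall outside the wet-bulb validity rectangle are kept with `tw_c = NA`
#' and a `flag`, never dropped silently.
#'
#' @param units Tibble with `site_id`, `unit_id`, `placement`, `timestamp`,
#'   `adj_temperature_c`, `vapour_pressure_hpa`, `relative_humidity_pct`,
#'   `dew_point_c`.
#' @param wind,solar Outdoor wind (m/s) and global horizontal irradiance
#'   (W/m2): scalars or per-record vectors aligned with the outdoor subset
#'   order. `NULL` leaves outdoor WBGT missing.
#' @param latitude,longitude Coordinates for the per-record solar zenith.
#' @param pressure Barometric pressure, hPa.
#' @return The input with `tw_c`, `wbgt_c` and `flag` columns appended.
#' @export
build_thermal_records <- function(units, wind = NULL, solar = NULL,
                                  latitude = STUDY_LATITUDE,
                                  longitude = STUDY_LONGITUDE,
                                  pressure = 1013) {
  units <- as_tibble(units)
  t <- units$adj_temperature_c
  rh <- units$relative_humidity_pct
  flag <- rep(NA_character_, nrow(units))
  invalid <- !is.na(t) & !is.na(rh) & rh <= 99 &
    (t < -20 | t > 50 | rh < 5)
  flag[invalid] <- "tw_out_of_range"
  units$tw_c <- stull_wet_bulb(t, rh, on_invalid = "flag")
  units$flag <- flag

  # dew point cannot exceed the unit's own temperature once RH is capped
  td <- pmin(units$dew_point_c, t)
  units$wbgt_c <- NA_real_
  house <- which(units$placement == "house" & !is.na(t) & !is.na(td))
  if (length(house) > 0) {
    units$wbgt_c[house] <-
      bernard_indoor_wbgt(t[house], td[house], wind = 1,
                          pressure = pressure)$wbgt
  }
  outdoor <- which(units$placement == "outdoor" & !is.na(t) & !is.na(td))
  if (length(outdoor) > 0 && !is.null(wind) && !is.null(solar)) {
    zen <- solar_position(latitude, longitude, units$timestamp[outdoor])
    units$wbgt_c[outdoor] <-
      liljegren_wbgt(t[outdoor], td[outdoor],
                     wind = rep_len(wind, length(outdoor)),
                     solar = rep_len(solar, length(outdoor)),
                     zenith = zen, pressure = pressure)$wbgt
  }
  units
}

#' Run the full logger processing pipeline
#'
#' Orchestrates [percentile_adjust()], [joint_validity_filter()],
#' [house_hourly_mean()], [settlement_median_vp()],
#' [reconstruct_humidity()] and [build_thermal_records()] and collects a
#' processing report of capping and attrition per settlement.
#'
#' @inheritParams percentile_adjust
#' @inheritParams build_thermal_records
#' @return A list with `records` (thermal records: one row per unit-hour)
#'   and `report` (list of `adjustment`, `validity`, `n_missing_vp`).
#' @export
process_loggers <- function(records, quantile = 0.95,
                            grouping = c("settlement", "citywide"),
                            wind = NULL, solar = NULL,
                            latitude = STUDY_LATITUDE,
                            longitude = STUDY_LONGITUDE,
                            pressure = 1013) {
  grouping <- match.arg(grouping)
  adj <- percentile_adjust(records, quantile = quantile, grouping = grouping)
  filt <- joint_validity_filter(adj$records)
  houses <- house_hourly_mean(filt$records)
  outdoor <- filt$records |>
    filter(.data$placement == "outdoor", !is.na(.data$adj_temperature_c)) |>
    transmute(.data$site_id, unit_id = .data$logger_id,
              placement = "outdoor", .data$timestamp,
              .data$adj_temperature_c, n_loggers = 1L)
  vp <- settlement_median_vp(filt$records)
  units <- bind_rows(houses, outdoor) |>
    left_join(vp |> select("site_id", "timestamp", "vapour_pressure_hpa"),
              by = c("site_id", "timestamp"))
  n_missing_vp <- sum(is.na(units$vapour_pressure_hpa))
  units <- filter(units, !is.na(.data$vapour_pressure_hpa))
  rec <- reconstruct_humidity(units$adj_temperature_c,
                              units$vapour_pressure_hpa)
  units$relative_humidity_pct <- rec$relative_humidity_pct
  units$dew_point_c <- rec$dew_point_c
  thermal <- build_thermal_records(units, wind = wind, solar = solar,
                                   latitude = latitude,
                                   longitude = longitude,
                                   pressure = pressure) |>
    arrange(.data$site_id, .data$unit_id, .data$timestamp)
  list(
    records = thermal,
    report = list(
      adjustment = adj$report,
      validity = filt$report,
      n_missing_vp = n_missing_vp
    )
  )
}

#' Write thermal records to CSV
#'
#' @param records Thermal-record tibble from [process_loggers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thermal_csv <- function(records, path) {
  out <- records
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = TZ_LOCAL)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
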