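# Seeded synthetic logger-network and weather-station generator with known
# ground truth. The process model is deliberately simple (sinusoidal diurnal
# cycle plus smooth seasonal drift, damped/lagged house transform, Gaussian
# sensor noise, positive daytime contamination spikes, block missingness):
# the tests need controllable truth, not microclimate realism.

#' Simulation configuration
#'
#' Defaults mirror the monitored network: 12 settlements, five outdoor
#' temperature+RH loggers each, ten houses each hosting three pairs of
#' temperature-only loggers (one member hourly, one two-hourly). The
#' default climate is a tropical coastal wet season (mean 28 degC,
#' 3.5 degC diurnal amplitude peaking at 14:00, vapour pressure around
#' 26 hPa peaking in the early morning). Houses damp the diurnal amplitude,
#' lag it and run slightly warm, so simulated houses are cooler than
#' outdoors by day and warmer by night. The default window is 14 days, a
#' desk-scale slice of the ~7-month deployment.
#'
#' @param seed Integer seed; all randomness derives from it through
#'   per-unit sub-streams, so adding a unit never perturbs another.
#' @param n_settlements,outdoor_per_settlement,houses_per_settlement,pairs_per_house
#'   Network structure counts.
#' @param start_date First local date of the window.
#' @param n_days Number of days.
#' @param climate List: `mean_t`, `diurnal_amplitude`, `peak_hour`,
#'   `mean_vp`, `vp_amplitude`, `vp_peak_hour`, `seasonal_drift` (degC
#'   amplitude of a slow drift), `settlement_spread` (degC half-range of
#'   fixed settlement offsets).
#' @param house List: `amplitude_damping` in (0,1], `phase_lag` hours,
#'   `warm_bias` degC.
#' @param noise_sd Gaussian sensor noise SD, degC.
#' @param contamination List: `fraction` of outdoor daytime records
#'   receiving a positive spike (default 0.02, inside the 5% headroom of
#'   the 95th-percentile cap), `spike_mean`, `spike_sd` degC.
#' @param missingness List: `block_rate` (probability a unit-day loses a
#'   block), `block_length` hours.
#' @param station List: `ids`, `offset` (degC subtracted from the
#'   settlement-mean truth), `cadence` hours, `noise_sd`, `qc_fail_rate`.
#' @param wbgt List: constant `wind` (m/s) and `solar` (W/m2) used for
#'   outdoor WBGT in both the truth tables and the matching pipeline runs.
#' @return A validated config list of class `heat_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_settlements = 12L,
                       outdoor_per_settlement = 5L,
                       houses_per_settlement = 10L,
                       pairs_per_house = 3L,
                       start_date = as.Date("2019-03-01"),
                       n_days = 14L,
                       climate = list(),
                       house = list(),
                       noise_sd = 0.3,
                       contamination = list(),
                       missingness = list(),
                       station = list(),
                       wbgt = list()) {
  cfg <- list(
    seed = as.integer(seed),
    n_settlements = as.integer(n_settlements),
    outdoor_per_settlement = as.integer(outdoor_per_settlement),
    houses_per_settlement = as.integer(houses_per_settlement),
    pairs_per_house = as.integer(pairs_per_house),
    start_date = as.Date(start_date),
    n_days = as.integer(n_days),
    climate = utils::modifyList(list(
      mean_t = 28, diurnal_amplitude = 3.5, peak_hour = 14,
      mean_vp = 26, vp_amplitude = 1.5, vp_peak_hour = 6,
      seasonal_drift = 0.5, settlement_spread = 0.8), climate),
    house = utils::modifyList(list(
      amplitude_damping = 0.5, phase_lag = 3, warm_bias = 0.5), house),
    noise_sd = noise_sd,
    contamination = utils::modifyList(list(
      fraction = 0.02, spike_mean = 3, spike_sd = 1), contamination),
    missingness = utils::modifyList(list(
      block_rate = 0.05, block_length = 6), missingness),
    station = utils::modifyList(list(
      ids = c("971800", "971840", "971820"), offset = 1.3,
      cadence = 1L, noise_sd = 0.3, qc_fail_rate = 0.02), station),
    wbgt = utils::modifyList(list(wind = 1, solar = 0), wbgt)
  )
  stopifnot(
    cfg$n_settlements > 0, cfg$outdoor_per_settlement > 0,
    cfg$houses_per_settlement > 0, cfg$pairs_per_house > 0, cfg$n_days > 0,
    cfg$house$amplitude_damping > 0, cfg$house$amplitude_damping <= 1,
    cfg$noise_sd >= 0, cfg$contamination$fraction >= 0,
    cfg$contamination$fraction <= 1, cfg$missingness$block_rate >= 0,
    cfg$missingness$block_rate <= 1, cfg$station$cadence >= 1,
    cfg$wbgt$wind > 0, cfg$wbgt$solar >= 0
  )
  class(cfg) <- "heat_sim_config"
  cfg
}

sim_hours <- function(config) {
  start <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = TZ_LOCAL)
  start + 3600 * (seq_len(config$n_days * 24L) - 1L)
}

settlement_ids <- function(config) {
  sprintf("S%02d", seq_len(config$n_settlements))
}

settlement_offsets <- function(config) {
  s <- config$climate$settlement_spread
  n <- config$n_settlements
  if (n == 1) return(0)
  seq(-s, s, length.out = n)
}

# Noiseless settlement processes on an hourly grid (local time).
sim_truth_series <- function(config, offset, ts) {
  cl <- config$climate
  hour_frac <- local_hour(ts)   # diurnal phase on the local clock
  day_idx <- as.numeric(difftime(ts, ts[1], units = "days"))
  drift <- cl$seasonal_drift * sin(2 * pi * day_idx / 180)
  diurnal <- cl$diurnal_amplitude *
    cos(2 * pi * (hour_frac - cl$peak_hour) / 24)
  t_out <- cl$mean_t + offset + drift + diurnal
  hs <- config$house
  diurnal_house <- hs$amplitude_damping * cl$diurnal_amplitude *
    cos(2 * pi * (hour_frac - cl$peak_hour - hs$phase_lag) / 24)
  t_house <- cl$mean_t + offset + drift + hs$warm_bias + diurnal_house
  vp <- cl$mean_vp + 0.2 * offset +
    cl$vp_amplitude * cos(2 * pi * (hour_frac - cl$vp_peak_hour) / 24)
  tibble(timestamp = ts, t_out = t_out, t_house = t_house, vp = vp)
}

truth_tw_wbgt <- function(t_true, vp, placement, config) {
  rh <- relative_humidity_from_vp(t_true, vp)
  tw <- stull_wet_bulb(t_true, rh)
  td <- pmin(dew_point(vp), t_true)
  wbgt <- numeric(length(t_true))
  hh <- placement == "house"
  if (any(hh)) {
    wbgt[hh] <- bernard_indoor_wbgt(t_true[hh], td[hh], wind = 1)$wbgt
  }
  if (any(!hh)) {
    wbgt[!hh] <- liljegren_wbgt(t_true[!hh], td[!hh],
                                wind = config$wbgt$wind,
                                solar = config$wbgt$solar,
                                zenith = 90)$wbgt
  }
  list(rh = rh, tw = tw, wbgt = wbgt)
}

#' Simulate the logger network
#'
#' Generates observations (truth plus Gaussian noise; outdoor loggers
#' report RH computed from the true vapour pressure and their observed
#' temperature; two-hourly pair members emit even hours only; block
#' missingness removes whole stretches of unit-days) together with the
#' noiseless truth tables the recovery tests compare against.
#'
#' @param config A [sim_config()].
#' @return A list: `records` (logger records), `truth` (list of
#'   `unit_hours` - per unit-hour true temperature, vapour pressure, RH,
#'   TW and WBGT - and `settlement_summary` - per-settlement true
#'   threshold fractions and daily maximum TW).
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "heat_sim_config"))
  ts <- sim_hours(config)
  sites <- settlement_ids(config)
  offsets <- settlement_offsets(config)
  thresholds <- activity_thresholds()

  rec_list <- list()
  truth_list <- list()
  for (si in seq_along(sites)) {
    site <- sites[si]
    tr <- sim_truth_series(config, offsets[si], ts)

    # ---- outdoor loggers ----
    for (k in seq_len(config$outdoor_per_settlement)) {
      lid <- sprintf("%s-O%d", site, k)
      set.seed(substream_seed(config$seed, si * 1000L + k))
      t_obs <- tr$t_out + rnorm(length(ts), 0, config$noise_sd)
      rh_obs <- relative_humidity_from_vp(t_obs, tr$vp)
      keep <- sim_keep_mask(length(ts), config)
      rec_list[[length(rec_list) + 1]] <- tibble(
        logger_id = lid, site_id = site, placement = "outdoor",
        house_id = NA_character_, timestamp = ts,
        temperature_c = t_obs, rh_pct = rh_obs
      )[keep, ]
      truth_list[[length(truth_list) + 1]] <- tibble(
        site_id = site, unit_id = lid, placement = "outdoor",
        timestamp = ts, t_true = tr$t_out, vp_true = tr$vp
      )
    }

    # ---- house loggers ----
    n_lgr <- 2L * config$pairs_per_house
    for (h in seq_len(config$houses_per_settlement)) {
      hid <- sprintf("%s-H%02d", site, h)
      for (j in seq_len(n_lgr)) {
        lid <- sprintf("%s-L%d", hid, j)
        set.seed(substream_seed(config$seed,
                                si * 1000L + 10L + (h - 1L) * n_lgr + j))
        t_obs <- tr$t_house + rnorm(length(ts), 0, config$noise_sd)
        two_hourly <- j > config$pairs_per_house
        cadence_ok <- if (two_hourly) local_hour(ts) %% 2L == 0L else
          rep(TRUE, length(ts))
        keep <- sim_keep_mask(length(ts), config) & cadence_ok
        rec_list[[length(rec_list) + 1]] <- tibble(
          logger_id = lid, site_id = site, placement = "house",
          house_id = hid, timestamp = ts,
          temperature_c = t_obs, rh_pct = NA_real_
        )[keep, ]
      }
      truth_list[[length(truth_list) + 1]] <- tibble(
        site_id = site, unit_id = hid, placement = "house",
        timestamp = ts, t_true = tr$t_house, vp_true = tr$vp
      )
    }
  }
  records <- bind_rows(rec_list)
  unit_hours <- bind_rows(truth_list)
  tt <- truth_tw_wbgt(unit_hours$t_true, unit_hours$vp_true,
                      unit_hours$placement, config)
  unit_hours$rh_true <- tt$rh
  unit_hours$tw_true <- tt$tw
  unit_hours$wbgt_true <- tt$wbgt

  fractions <- bind_rows(lapply(names(thresholds), function(lab) {
    unit_hours |>
      group_by(.data$site_id) |>
      summarise(threshold_label = lab,
                threshold = thresholds[[lab]],
                fraction_true = mean(.data$wbgt_true >= thresholds[[lab]]),
                .groups = "drop")
  }))
  daily_max <- unit_hours |>
    mutate(date = local_date(.data$timestamp)) |>
    group_by(.data$site_id, .data$date) |>
    summarise(tw_max_true = max(.data$tw_true), .groups = "drop")

  list(records = records,
       truth = list(unit_hours = unit_hours,
                    settlement_summary = list(fractions = fractions,
                                              daily_max = daily_max)))
}

# Per-unit retention mask implementing block-wise missingness; call under
# the unit's RNG sub-stream (after the noise draws, so the draws are
# stable per unit).
sim_keep_mask <- function(n_hours, config) {
  keep <- rep(TRUE, n_hours)
  rate <- config$missingness$block_rate
  if (rate <= 0) return(keep)
  n_days <- ceiling(n_hours / 24L)
  lost <- runif(n_days) < rate
  starts <- sample.int(24L, n_days, replace = TRUE) - 1L
  for (d in which(lost)) {
    i0 <- (d - 1L) * 24L + starts[d] + 1L
    idx <- i0:min(i0 + config$missingness$block_length - 1L, n_hours)
    keep[idx] <- FALSE
  }
  keep
}

#' Inject solar-inflation contamination
#'
#' Adds strictly positive temperature spikes (truncated-normal) to a random
#' subset of outdoor daytime (06:00-18:00) records, emulating shield
#' heating under direct sun. The default 2% fraction stays inside the 5%
#' headroom of the 95th-percentile cap, so the adjustment can fully absorb
#' it; a fraction above the headroom triggers a warning.
#'
#' @param records Logger records from [simulate_network()].
#' @param config A [sim_config()].
#' @param quantile Capping quantile of the downstream adjustment (for the
#'   headroom warning only).
#' @return A list with `records` (contaminated) and `log` (tibble of
#'   `logger_id`, `timestamp`, `magnitude`).
#' @export
inject_contamination <- function(records, config, quantile = 0.95) {
  frac <- config$contamination$fraction
  if (frac > 1 - quantile) {
    warn(sprintf(
      "contamination fraction %.3f exceeds the %g-quantile headroom %.3f; the adjustment cannot fully absorb it.",
      frac, quantile, 1 - quantile))
  }
  log_empty <- tibble(logger_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = TZ_LOCAL),
                      magnitude = numeric(0))
  if (frac <= 0) return(list(records = records, log = log_empty))
  h <- local_hour(records$timestamp)
  candidates <- which(records$placement == "outdoor" & h >= 6 & h < 18)
  n_spike <- round(frac * length(candidates))
  if (n_spike == 0) return(list(records = records, log = log_empty))
  set.seed(substream_seed(config$seed, 999983L))
  hit <- sample(candidates, n_spike)
  m <- config$contamination$spike_mean
  s <- config$contamination$spike_sd
  # truncated normal, strictly positive spikes
  u <- runif(n_spike, pnorm(0, mean = m, sd = s), 1)
  spikes <- qnorm(u, mean = m, sd = s)
  records$temperature_c[hit] <- records$temperature_c[hit] + spikes
  list(records = records,
       log = tibble(logger_id = records$logger_id[hit],
                    timestamp = records$timestamp[hit],
                    magnitude = spikes))
}

#' Simulate weather-station records
#'
#' Station temperature is the settlement-mean outdoor truth minus the
#' configured offset plus Gaussian noise, emitted at the configured cadence
#' in UTC; dew point is consistent with the settlement-mean true vapour
#' pressure. A configurable fraction of records carries failing QC codes to
#' exercise the quality filter; those records are listed in the log.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_network()].
#' @return A list with `records` (station-record tibble, UTC timestamps)
#'   and `log` (QC-failed records).
#' @export
simulate_station <- function(config, truth) {
  base <- truth$unit_hours |>
    filter(.data$placement == "outdoor") |>
    distinct(.data$site_id, .data$timestamp, .data$t_true, .data$vp_true) |>
    group_by(.data$timestamp) |>
    summarise(t_mean = mean(.data$t_true), vp_mean = mean(.data$vp_true),
              .groups = "drop")
  ts_utc <- base$timestamp
  attr(ts_utc, "tzone") <- "UTC"
  on_cadence <- as.integer(format(ts_utc, "%H", tz = "UTC")) %%
    config$station$cadence == 0L
  rec_list <- list()
  log_list <- list()
  for (k in seq_along(config$station$ids)) {
    sid <- config$station$ids[k]
    set.seed(substream_seed(config$seed, 500000L + k))
    noise <- rnorm(nrow(base), 0, config$station$noise_sd)
    qc_fail <- runif(nrow(base)) < config$station$qc_fail_rate
    temp <- base$t_mean - config$station$offset + noise
    rec <- tibble(
      station_id = sid,
      timestamp_utc = ts_utc,
      temperature_c = round(temp, 1),           # ISD tenths resolution
      dew_point_c = round(pmin(dew_point(base$vp_mean), temp), 1),
      temperature_qc = ifelse(qc_fail, "3", "1"),
      dew_point_qc = "1"
    )[on_cadence, ]
    rec_list[[k]] <- rec
    log_list[[k]] <- rec |>
      filter(.data$temperature_qc != "1") |>
      select("station_id", "timestamp_utc")
  }
  list(records = bind_rows(rec_list), log = bind_rows(log_list))
}

#' Write simulated fixtures to disk
#'
#' Logger CSV per the pipeline interface, one ISD-Lite fixed-width file per
#' station, truth tables as CSV, and the configuration echoed as JSON.
#'
#' @param records Logger records.
#' @param station_records Station records.
#' @param out_dir Output directory (created if needed).
#' @param truth Optional truth list to write.
#' @param config Optional config to echo.
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixtures <- function(records, station_records, out_dir,
                           truth = NULL, config = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      abort(sprintf("cannot create output directory '%s'.", out_dir))
    }
  }
  files <- c(loggers = file.path(out_dir, "loggers.csv"))
  write_logger_csv(records, files[["loggers"]])
  for (sid in unique(station_records$station_id)) {
    yr <- format(min(station_records$timestamp_utc), "%Y", tz = "UTC")
    f <- file.path(out_dir, sprintf("%s-99999-%s.txt", sid, yr))
    write_isd_lite(station_records[station_records$station_id == sid, ], f)
    files[sid] <- f
  }
  if (!is.null(truth)) {
    uh <- truth$unit_hours
    uh$timestamp <- format(uh$timestamp, "%Y-%m-%dT%H:%M:%S", tz = TZ_LOCAL)
    readr::write_csv(uh, file.path(out_dir, "truth_unit_hours.csv"),
                     progress = FALSE)
    readr::write_csv(truth$settlement_summary$fractions,
                     file.path(out_dir, "truth_fractions.csv"),
                     progress = FALSE)
    readr::write_csv(truth$settlement_summary$daily_max,
                     file.path(out_dir, "truth_daily_max.csv"),
                     progress = FALSE)
    files["truth_unit_hours"] <- file.path(out_dir, "truth_unit_hours.csv")
  }
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$start_date <- as.character(cfg$start_date)
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    files["config"] <- file.path(out_dir, "config.json")
  }
  invisible(files)
}
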