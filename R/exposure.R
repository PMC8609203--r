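# Exposure summaries: daily maximum wet bulb with earliest-record
# tie-breaking, gap-tolerant exceedance runs over WBGT activity thresholds,
# threshold-band frequencies, day/night stratification and the in-situ vs
# weather-station comparison.

#' ISO 7243 derived WBGT activity thresholds
#'
#' Reference WBGT limits (degC) by metabolic work class for an acclimatised
#' person: heavy work 25, moderate/light work 28, light work 30, resting 33.
#' The 25 degC band is the lowest at which health and productivity effects
#' are reported across occupations.
#'
#' @return A named numeric vector, strictly increasing.
#' @export
activity_thresholds <- function() {
  c(heavy_work = 25, moderate_light_work = 28, light_work = 30, resting = 33)
}

check_thresholds <- function(thresholds) {
  if (is.null(names(thresholds)) || any(names(thresholds) == "")) {
    names(thresholds) <- paste0("wbgt_", thresholds)
  }
  if (any(diff(thresholds) <= 0)) {
    abort("`thresholds` must be strictly increasing.")
  }
  thresholds
}

#' Daily maximum wet bulb temperature
#'
#' Per unit and local calendar date, the maximum of the series; equal
#' highest values resolve to the record occurring earliest in the day.
#' Empty days are absent from the output.
#'
#' @param series Tibble with columns `unit_id`, `timestamp`, and the value
#'   column named by `value_col` (default `"tw_c"`).
#' @param value_col Name of the value column.
#' @return A tibble with `unit_id`, `date`, `value`, `at` (timestamp of the
#'   maximum).
#' @export
daily_max_tw <- function(series, value_col = "tw_c") {
  series |>
    filter(!is.na(.data[[value_col]])) |>
    mutate(date = local_date(.data$timestamp)) |>
    group_by(.data$unit_id, .data$date) |>
    arrange(.data$timestamp, .by_group = TRUE) |>
    summarise(
      value = max(.data[[value_col]]),
      at = .data$timestamp[which.max(.data[[value_col]])],
      .groups = "drop"
    )
}

#' Continuous periods above a WBGT threshold
#'
#' Scans one unit's time-sorted WBGT series for maximal runs of records at
#' or above `threshold`. Consecutive above-threshold records may be up to
#' `max_gap` hours apart, bridging periods where only 2-hourly data were
#' recovered; the bridge applies to *missing* records only - an observed
#' below-threshold record always terminates a run. Run duration counts
#' bridged clock hours (`end - start + 1` recording hour); `n_records`
#' counts observed above-threshold records; `n_bridged_gaps` counts
#' bridged between-record gaps longer than one hour.
#'
#' @param series Tibble for a single unit with `timestamp` and the column
#'   named by `value_col`; must be sorted by time. Rows with missing values
#'   are treated as absent records.
#' @param threshold WBGT threshold, degC.
#' @param max_gap Maximum bridgeable gap, hours (default 2).
#' @param value_col Name of the value column (default `"wbgt_c"`).
#' @return A tibble of runs: `threshold`, `start`, `end`, `duration_h`,
#'   `n_records`, `n_bridged_gaps`; zero rows when nothing exceeds.
#' @export
exceedance_runs <- function(series, threshold, max_gap = 2,
                            value_col = "wbgt_c") {
  ts <- series$timestamp
  if (is.unsorted(ts, strictly = FALSE)) {
    abort("`series` must be sorted by `timestamp`.")
  }
  v <- series[[value_col]]
  keep <- !is.na(v)
  ts <- ts[keep]
  v <- v[keep]
  empty <- tibble(
    threshold = numeric(0),
    start = as.POSIXct(character(0), tz = TZ_LOCAL),
    end = as.POSIXct(character(0), tz = TZ_LOCAL),
    duration_h = numeric(0), n_records = integer(0),
    n_bridged_gaps = integer(0)
  )
  if (length(v) == 0) return(empty)

  above <- v >= threshold
  runs <- list()
  start <- NA; end <- NA; n_rec <- 0L; n_gap <- 0L
  close_run <- function() {
    runs[[length(runs) + 1]] <<- tibble(
      threshold = threshold, start = start, end = end,
      duration_h = as.numeric(difftime(end, start, units = "hours")) + 1,
      n_records = n_rec, n_bridged_gaps = n_gap
    )
    start <<- NA
  }
  for (i in seq_along(v)) {
    if (!above[i]) {                       # observed cool record ends a run
      if (!is.na(start)) close_run()
      next
    }
    if (is.na(start)) {
      start <- ts[i]; end <- ts[i]; n_rec <- 1L; n_gap <- 0L
    } else {
      gap <- as.numeric(difftime(ts[i], end, units = "hours"))
      if (gap <= max_gap) {
        if (gap > 1) n_gap <- n_gap + 1L
        end <- ts[i]; n_rec <- n_rec + 1L
      } else {
        close_run()
        start <- ts[i]; end <- ts[i]; n_rec <- 1L; n_gap <- 0L
      }
    }
  }
  if (!is.na(start)) close_run()
  if (length(runs) == 0) empty else bind_rows(runs)
}

#' Exceedance runs for every unit and threshold
#'
#' @param records Thermal-record tibble with `unit_id`, `timestamp` and the
#'   value column.
#' @param thresholds Named increasing thresholds, degC.
#' @inheritParams exceedance_runs
#' @return A tibble of runs with `unit_id` and `threshold_label` prepended.
#' @export
exceedance_runs_all <- function(records, thresholds = activity_thresholds(),
                                max_gap = 2, value_col = "wbgt_c") {
  thresholds <- check_thresholds(thresholds)
  units <- split(records, records$unit_id)
  out <- lapply(names(units), function(u) {
    s <- arrange(units[[u]], .data$timestamp)
    bind_rows(lapply(names(thresholds), function(lab) {
      r <- exceedance_runs(s, thresholds[[lab]], max_gap = max_gap,
                           value_col = value_col)
      if (nrow(r) > 0) mutate(r, unit_id = u, threshold_label = lab) else NULL
    }))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) return(out)
  select(out, "unit_id", "threshold_label", everything())
}

#' Run-length histogram
#'
#' Tabulates exceedance runs by threshold and integer duration, plus the
#' count of runs longer than each stated cut-off (e.g. more than 5
#' consecutive hours).
#'
#' @param runs Run tibble from [exceedance_runs_all()] (needs `threshold`
#'   and `duration_h`).
#' @param cutoffs Durations (hours) for the "longer than" counts.
#' @return A list with `histogram` (counts by threshold and duration) and
#'   `over_cutoff` (counts of runs exceeding each cut-off per threshold).
#' @export
run_length_histogram <- function(runs, cutoffs = 5) {
  if (nrow(runs) == 0) {
    return(list(
      histogram = tibble(threshold = numeric(0), duration_h = numeric(0),
                         n_runs = integer(0)),
      over_cutoff = tibble(threshold = numeric(0), cutoff_h = numeric(0),
                           n_runs = integer(0))
    ))
  }
  histogram <- runs |>
    count(.data$threshold, duration_h = floor(.data$duration_h),
          name = "n_runs")
  over <- bind_rows(lapply(cutoffs, function(ct) {
    runs |>
      group_by(.data$threshold) |>
      summarise(cutoff_h = ct, n_runs = sum(.data$duration_h > ct),
                .groups = "drop")
  }))
  list(histogram = histogram, over_cutoff = over)
}

#' Fraction of records per WBGT band
#'
#' Partitions records into half-open bands \eqn{[t_i, t_{i+1})} bounded by
#' the activity thresholds, plus a below-lowest and an at-or-above-highest
#' band (fractions sum to 1), and reports the cumulative fraction of
#' records at or above each threshold.
#'
#' @param values Numeric WBGT values (missing values are dropped).
#' @param thresholds Named increasing thresholds, degC.
#' @return A list with `bands` (`band`, `n`, `fraction`) and `cumulative`
#'   (`threshold_label`, `threshold`, `fraction_ge`).
#' @export
band_frequencies <- function(values, thresholds = activity_thresholds()) {
  thresholds <- check_thresholds(thresholds)
  values <- values[!is.na(values)]
  breaks <- c(-Inf, unname(thresholds), Inf)
  labs <- c(sprintf("<%g", thresholds[1]),
            sprintf("[%g,%g)", head(thresholds, -1), tail(thresholds, -1)),
            sprintf(">=%g", tail(thresholds, 1)))
  bins <- cut(values, breaks = breaks, labels = labs, right = FALSE)
  bands <- tibble(band = labs,
                  n = as.integer(table(bins)[labs]),
                  fraction = as.integer(table(bins)[labs]) /
                    max(length(values), 1L))
  cumulative <- tibble(
    threshold_label = names(thresholds),
    threshold = unname(thresholds),
    fraction_ge = unname(vapply(thresholds, function(t) mean(values >= t), 0))
  )
  list(bands = bands, cumulative = cumulative)
}

#' Split records into day and night
#'
#' Partition by the local clock window; the default day window is
#' 06:00-18:00 (exclusive of 18:00), the near-constant equatorial daylight
#' period.
#'
#' @param records Tibble with a `timestamp` column.
#' @param day_start,day_end Local hours bounding the day window.
#' @return A list with `day` and `night` tibbles; exhaustive and disjoint.
#' @export
day_night_split <- function(records, day_start = 6, day_end = 18) {
  h <- local_hour(records$timestamp)
  is_day <- h >= day_start & h < day_end
  list(day = records[is_day, , drop = FALSE],
       night = records[!is_day, , drop = FALSE])
}

#' Compare in-situ and weather-station daily maxima
#'
#' Pairs each day's in-situ maximum (the maximum over the supplied in-situ
#' units) with the same-day station-side value: by default the maximum
#' across stations, with per-station pairings also reported. Days absent
#' from either side are excluded and counted.
#'
#' @param in_situ Daily-maximum tibble ([daily_max_tw()]) for in-situ units.
#' @param station Daily-maximum tibble for stations (`unit_id` = station).
#' @return A list: `differences` (per-day paired values and `difference` =
#'   in-situ minus station), `mean_difference`, `per_station` (mean
#'   difference against each station), `n_unmatched_in_situ`,
#'   `n_unmatched_station`.
#' @export
station_comparison <- function(in_situ, station) {
  situ_daily <- in_situ |>
    group_by(.data$date) |>
    summarise(in_situ = max(.data$value), .groups = "drop")
  stat_daily <- station |>
    group_by(.data$date) |>
    summarise(station = max(.data$value), .groups = "drop")
  paired <- inner_join(situ_daily, stat_daily, by = "date") |>
    mutate(difference = .data$in_situ - .data$station)
  if (nrow(paired) == 0) {
    abort("no overlapping days between in-situ and station series.")
  }
  per_station <- station |>
    group_by(.data$date, .data$unit_id) |>
    summarise(station = max(.data$value), .groups = "drop") |>
    inner_join(situ_daily, by = "date") |>
    group_by(.data$unit_id) |>
    summarise(mean_difference = mean(.data$in_situ - .data$station),
              n_days = n(), .groups = "drop")
  list(
    differences = paired,
    mean_difference = mean(paired$difference),
    per_station = per_station,
    n_unmatched_in_situ = nrow(situ_daily) - nrow(paired),
    n_unmatched_station = nrow(stat_daily) - nrow(paired)
  )
}

#' Headline exposure summary
#'
#' Aggregates the exposure statistics of a thermal-record table: cumulative
#' threshold fractions, the longest run per threshold, and run counts over
#' the 5-hour cut-off.
#'
#' @param records Thermal records with `unit_id`, `timestamp`, `wbgt_c`.
#' @param thresholds Named increasing thresholds, degC.
#' @param max_gap Bridgeable gap for runs, hours.
#' @return A list with `fractions`, `runs`, `longest`, `over_5h`.
#' @export
exposure_summary <- function(records, thresholds = activity_thresholds(),
                             max_gap = 2) {
  thresholds <- check_thresholds(thresholds)
  bf <- band_frequencies(records$wbgt_c, thresholds)
  runs <- exceedance_runs_all(records, thresholds, max_gap = max_gap)
  longest <- if (nrow(runs) > 0) {
    runs |>
      group_by(.data$threshold_label, .data$threshold) |>
      summarise(longest_h = max(.data$duration_h), n_runs = n(),
                .groups = "drop")
  } else {
    tibble(threshold_label = character(0), threshold = numeric(0),
           longest_h = numeric(0), n_runs = integer(0))
  }
  over5 <- run_length_histogram(runs, cutoffs = 5)$over_cutoff
  list(fractions = bf$cumulative, bands = bf$bands, runs = runs,
       longest = longest, over_5h = over5)
}
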