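# Weather-station ingestion in the Integrated Surface Database (ISD)
# dialects: ISD-Lite fixed-width hourly files (primary) and the full ISD
# mandatory section (read-only), with per-field quality codes, QC
# filtering, hourly averaging and station wet bulb.

ISD_MISSING <- -9999
# full-ISD quality codes meaning "passed all quality control checks"
ISD_QC_PASS <- c("1", "5")

#' Read weather-station records (ISD dialects)
#'
#' Reads either ISD-Lite fixed-width hourly files (whitespace-separated
#' `year month day hour T*10 Td*10 ...`, sentinel -9999) or full-ISD lines
#' (mandatory section, fixed character positions, with per-field quality
#' codes). The dialect is auto-detected per file. ISD-Lite data are already
#' quality-controlled upstream, so their QC codes are recorded as passing.
#' Timestamps are carried as UTC. Malformed lines are skipped and counted
#' in the `skipped` attribute.
#'
#' @param path Path to a station file (optionally gzip-compressed).
#' @param station_id Station identifier; defaults to the leading
#'   digit-group of the file name (e.g. `971800-99999-2019` -> `971800`).
#' @param dialect `"auto"` (default), `"isd_lite"` or `"isd_full"`.
#' @return A tibble with `station_id`, `timestamp_utc`, `temperature_c`,
#'   `dew_point_c`, `temperature_qc`, `dew_point_qc`; attribute `skipped`
#'   holds the malformed-line count.
#' @export
read_isd <- function(path, station_id = NULL,
                     dialect = c("auto", "isd_lite", "isd_full")) {
  dialect <- match.arg(dialect)
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) abort(sprintf(
                      "cannot read station file '%s': %s", path,
                      conditionMessage(e))))
  lines <- lines[nzchar(trimws(lines))]
  if (is.null(station_id)) {
    m <- regmatches(basename(path), regexpr("^[0-9]+", basename(path)))
    station_id <- if (length(m) > 0 && nzchar(m)) m else "unknown"
  }
  if (dialect == "auto") {
    # full ISD mandatory lines are >= 105 chars and start with the
    # 4-char variable-length field + station ids, with no space before
    # position 13; ISD-Lite lines are short and whitespace-separated.
    dialect <- if (length(lines) > 0 && nchar(lines[1]) >= 105 &&
                     !grepl("^\\s*\\d{4}\\s", lines[1]))
      "isd_full" else "isd_lite"
  }
  if (dialect == "isd_lite") {
    parse_isd_lite(lines, station_id)
  } else {
    parse_isd_full(lines, station_id)
  }
}

parse_isd_lite <- function(lines, station_id) {
  skipped <- 0L
  rows <- lapply(lines, function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 6 || anyNA(suppressWarnings(as.numeric(f[1:6])))) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    n <- as.numeric(f[1:6])
    list(year = n[1], month = n[2], day = n[3], hour = n[4],
         t10 = n[5], td10 = n[6])
  })
  skipped_n <- skipped
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    out <- empty_station_tbl()
    attr(out, "skipped") <- skipped_n
    return(out)
  }
  d <- bind_rows(lapply(rows, as_tibble))
  out <- tibble(
    station_id = station_id,
    timestamp_utc = as.POSIXct(
      sprintf("%04d-%02d-%02d %02d:00:00", d$year, d$month, d$day, d$hour),
      tz = "UTC"),
    temperature_c = ifelse(d$t10 == ISD_MISSING, NA_real_, d$t10 / 10),
    dew_point_c = ifelse(d$td10 == ISD_MISSING, NA_real_, d$td10 / 10),
    temperature_qc = "1",
    dew_point_qc = "1"
  )
  attr(out, "skipped") <- skipped_n
  out
}

parse_isd_full <- function(lines, station_id) {
  ok <- nchar(lines) >= 99
  skipped_n <- sum(!ok)
  lines <- lines[ok]
  if (length(lines) == 0) {
    out <- empty_station_tbl()
    attr(out, "skipped") <- skipped_n
    return(out)
  }
  usaf <- substr(lines, 5, 10)
  date <- substr(lines, 16, 23)
  hhmm <- substr(lines, 24, 27)
  t_raw <- suppressWarnings(as.numeric(substr(lines, 88, 92)))
  t_qc <- substr(lines, 93, 93)
  td_raw <- suppressWarnings(as.numeric(substr(lines, 94, 98)))
  td_qc <- substr(lines, 99, 99)
  out <- tibble(
    station_id = ifelse(nzchar(trimws(usaf)), trimws(usaf), station_id),
    timestamp_utc = as.POSIXct(paste0(date, " ", hhmm),
                               format = "%Y%m%d %H%M", tz = "UTC"),
    temperature_c = ifelse(is.na(t_raw) | t_raw == 9999, NA_real_,
                           t_raw / 10),
    dew_point_c = ifelse(is.na(td_raw) | td_raw == 9999, NA_real_,
                         td_raw / 10),
    temperature_qc = t_qc,
    dew_point_qc = td_qc
  )
  bad <- is.na(out$timestamp_utc)
  attr(out, "skipped") <- skipped_n + sum(bad)
  out[!bad, , drop = FALSE]
}

empty_station_tbl <- function() {
  tibble(
    station_id = character(0),
    timestamp_utc = as.POSIXct(character(0), tz = "UTC"),
    temperature_c = numeric(0), dew_point_c = numeric(0),
    temperature_qc = character(0), dew_point_qc = character(0)
  )
}

#' Write station records as ISD-Lite fixed-width text
#'
#' Emits the eight leading ISD-Lite fields (`year month day hour T*10 Td*10
#' SLP*10 WSPD*10`, the last two as the -9999 sentinel here), one file
#' readable by [read_isd()]. Records whose quality codes are not in the
#' accepted set are still written; the codes live in the full-ISD dialect
#' only, so callers wanting to exercise QC filtering should use
#' [write_isd_full()].
#'
#' @param records Station-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isd_lite <- function(records, path) {
  enc <- function(x) ifelse(is.na(x), ISD_MISSING, round(x * 10))
  lines <- sprintf(
    "%04d %02d %02d %02d %6d %6d %6d %6d",
    as.integer(format(records$timestamp_utc, "%Y", tz = "UTC")),
    as.integer(format(records$timestamp_utc, "%m", tz = "UTC")),
    as.integer(format(records$timestamp_utc, "%d", tz = "UTC")),
    as.integer(format(records$timestamp_utc, "%H", tz = "UTC")),
    enc(records$temperature_c), enc(records$dew_point_c),
    ISD_MISSING, ISD_MISSING
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write station records as full-ISD mandatory-section lines
#'
#' Produces minimal mandatory-section lines with the temperature and dew
#' point fields (tenths of degC, sentinel +9999) and their quality codes at
#' the documented character positions, so that [read_isd()] and
#' [qc_filter()] can be exercised end to end.
#'
#' @param records Station-record tibble (with `temperature_qc`,
#'   `dew_point_qc`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isd_full <- function(records, path) {
  enc <- function(x) {
    ifelse(is.na(x), "+9999", sprintf("%+05d", as.integer(round(x * 10))))
  }
  head_part <- sprintf(
    "0000%6s99999%8s%4s4%+06.0f%+07.0f",
    substr(paste0(records$station_id, "      "), 1, 6),
    format(records$timestamp_utc, "%Y%m%d", tz = "UTC"),
    format(records$timestamp_utc, "%H%M", tz = "UTC"),
    0, 0
  )
  # pad out to position 87, then T (88-92) qc (93) Td (94-98) qc (99),
  # then fill to the 105-char mandatory-section length
  pad <- strrep("9", 87 - nchar(head_part[1]))
  lines <- paste0(
    head_part, pad,
    enc(records$temperature_c), records$temperature_qc,
    enc(records$dew_point_c), records$dew_point_qc,
    "999999"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Quality-control filter for station records
#'
#' Retains records whose temperature and dew-point quality codes are in the
#' accepted set ("passed all quality control checks"), whose dew point does
#' not exceed the temperature (consistency), and whose values lie inside
#' plausibility bounds. All removals are counted by reason; the filter is
#' idempotent.
#'
#' @param records Station-record tibble.
#' @param accepted Accepted QC codes (default `c("1", "5")`).
#' @param bounds Plausibility bounds for both fields, degC.
#' @return A list with `records` (retained) and `report` (counts per
#'   removal reason).
#' @export
qc_filter <- function(records, accepted = ISD_QC_PASS,
                      bounds = c(-30, 60)) {
  missing <- is.na(records$temperature_c) | is.na(records$dew_point_c)
  bad_qc <- !missing &
    (!(records$temperature_qc %in% accepted) |
       !(records$dew_point_qc %in% accepted))
  inconsistent <- !missing & !bad_qc &
    records$dew_point_c > records$temperature_c
  out_of_range <- !missing & !bad_qc & !inconsistent &
    (records$temperature_c < bounds[1] | records$temperature_c > bounds[2] |
       records$dew_point_c < bounds[1] | records$dew_point_c > bounds[2])
  keep <- !missing & !bad_qc & !inconsistent & !out_of_range
  report <- tibble(
    reason = c("missing_value", "failed_qc_code", "consistency",
               "out_of_range"),
    n_removed = c(sum(missing), sum(bad_qc), sum(inconsistent),
                  sum(out_of_range))
  )
  list(records = records[keep, , drop = FALSE], report = report)
}

#' Hourly aggregation of station records
#'
#' Where a station reports more than once per clock hour
#' (\eqn{[h{:}00, h{+}1{:}00)} bins), temperature and dew point are
#' averaged field-wise over the available values; single-record hours pass
#' through unchanged.
#'
#' @param records QC-filtered station records.
#' @return Hourly station records (QC codes collapse to "1").
#' @export
hourly_aggregate <- function(records) {
  records |>
    mutate(timestamp_utc = as.POSIXct(
      floor(as.numeric(.data$timestamp_utc) / 3600) * 3600,
      origin = "1970-01-01", tz = "UTC")) |>
    group_by(.data$station_id, .data$timestamp_utc) |>
    summarise(
      temperature_c = if (all(is.na(.data$temperature_c))) NA_real_ else
        mean(.data$temperature_c, na.rm = TRUE),
      dew_point_c = if (all(is.na(.data$dew_point_c))) NA_real_ else
        mean(.data$dew_point_c, na.rm = TRUE),
      temperature_qc = "1", dew_point_qc = "1",
      .groups = "drop"
    )
}

#' Station wet bulb temperature
#'
#' Recovers relative humidity from dew point
#' (\eqn{RH = 100\, e_s(T_d)/e_s(T)}, capped at 100), applies the Stull
#' wet bulb with the same saturation rule as the in-situ pipeline, and
#' converts timestamps to local civil time (UTC+8) for daily grouping.
#'
#' @param records Hourly station records.
#' @return A tibble with `unit_id` (the station), `timestamp` (local),
#'   `temperature_c`, `dew_point_c`, `rh_pct`, `tw_c`.
#' @export
station_tw <- function(records) {
  rh <- relative_humidity_from_vp(
    records$temperature_c,
    saturation_vapour_pressure(pmin(records$dew_point_c,
                                    records$temperature_c)))
  ts_local <- records$timestamp_utc
  attr(ts_local, "tzone") <- TZ_LOCAL
  tibble(
    unit_id = records$station_id,
    timestamp = ts_local,
    temperature_c = records$temperature_c,
    dew_point_c = records$dew_point_c,
    rh_pct = rh,
    tw_c = stull_wet_bulb(records$temperature_c, rh)
  )
}
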