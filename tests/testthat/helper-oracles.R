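# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the functions they verify.

TZ8 <- "Etc/GMT-8"

# Magnus curve written out locally (same published coefficients, written
# independently of the package internals).
es_magnus <- function(t) 6.1094 * exp(17.625 * t / (243.04 + t))

# Brute-force exceedance-run enumerator: above-threshold records are
# joinable when no observed record lies strictly between them and their
# spacing is at most max_gap hours. Formulated over index adjacency, unlike
# the package's sequential scan.
oracle_runs <- function(timestamp, value, threshold, max_gap = 2) {
  keep <- !is.na(value)
  ts <- timestamp[keep]
  v <- value[keep]
  idx <- which(v >= threshold)
  if (length(idx) == 0) {
    return(data.frame(start = as.POSIXct(character(0), tz = TZ8),
                      end = as.POSIXct(character(0), tz = TZ8),
                      duration_h = numeric(0), n_records = integer(0),
                      n_bridged_gaps = integer(0)))
  }
  joinable <- logical(length(idx) - 1)
  if (length(idx) > 1) {
    for (k in seq_len(length(idx) - 1)) {
      a <- idx[k]; b <- idx[k + 1]
      gap_h <- as.numeric(difftime(ts[b], ts[a], units = "hours"))
      joinable[k] <- (b == a + 1) && gap_h <= max_gap
    }
  }
  grp <- cumsum(c(1, !joinable))
  out <- lapply(split(idx, grp), function(ii) {
    gaps <- if (length(ii) > 1) {
      diff(as.numeric(ts[ii]) / 3600)
    } else numeric(0)
    data.frame(
      start = ts[ii[1]], end = ts[ii[length(ii)]],
      duration_h = as.numeric(difftime(ts[ii[length(ii)]], ts[ii[1]],
                                       units = "hours")) + 1,
      n_records = length(ii),
      n_bridged_gaps = sum(gaps > 1)
    )
  })
  do.call(rbind, out)
}

# Brute-force per-day maximum with earliest-record tie selection.
oracle_daily_max <- function(timestamp, value) {
  keep <- !is.na(value)
  ts <- timestamp[keep]
  v <- value[keep]
  dates <- as.Date(ts, tz = TZ8)
  out <- lapply(split(seq_along(v), dates), function(ii) {
    ii <- ii[order(ts[ii])]
    best <- ii[which.max(v[ii])]
    data.frame(date = as.Date(ts[best], tz = TZ8), value = v[best],
               at = ts[best])
  })
  res <- do.call(rbind, out)
  res[order(res$date), , drop = FALSE]
}

# Spencer (1971) Fourier-series solar ephemeris: an independent
# low-precision route to the solar zenith.
oracle_zenith <- function(latitude, longitude, timestamp) {
  doy <- as.numeric(format(timestamp, "%j", tz = "UTC"))
  hh <- as.numeric(format(timestamp, "%H", tz = "UTC")) +
    as.numeric(format(timestamp, "%M", tz = "UTC")) / 60
  g <- 2 * pi / 365 * (doy - 1 + (hh - 12) / 24)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  tst <- hh * 60 + eqtime + 4 * longitude
  ha <- (tst / 4 - 180) * pi / 180
  lat <- latitude * pi / 180
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  acos(pmin(1, pmax(-1, cosz))) * 180 / pi
}

# Random WBGT-like series on an hourly grid with random missingness.
random_series <- function(n_hours = 48, p_missing = 0.3,
                          lo = 20, hi = 36) {
  start <- as.POSIXct("2019-03-01 00:00:00", tz = TZ8)
  ts <- start + 3600 * (seq_len(n_hours) - 1)
  keep <- runif(n_hours) > p_missing
  data.frame(timestamp = ts[keep],
             wbgt_c = runif(sum(keep), lo, hi))
}

# Minimal logger-record table builder for pipeline tests.
logger_tbl <- function(logger_id, site_id, placement, house_id, hour,
                       temperature_c, rh_pct = NA_real_,
                       date = "2019-03-01") {
  data.frame(
    logger_id = logger_id, site_id = site_id, placement = placement,
    house_id = house_id,
    timestamp = as.POSIXct(paste(date, sprintf("%02d:00:00", hour)),
                           tz = TZ8),
    temperature_c = temperature_c, rh_pct = rh_pct,
    stringsAsFactors = FALSE
  )
}
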