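test_that("daily maximum takes the earliest record among equal highest", {
  s <- data.frame(
    unit_id = "u",
    timestamp = as.POSIXct(paste("2019-03-01", c("06:00", "13:00", "15:00")),
                           tz = TZ8),
    tw_c = c(29.1, 30.0, 30.0)
  )
  dm <- daily_max_tw(s)
  expect_equal(dm$value, 30.0)
  expect_equal(dm$at, s$timestamp[2])
  solo <- s[1, ]
  expect_equal(daily_max_tw(solo)$value, 29.1)
})

test_that("daily maximum equals the brute-force scan on random multi-day series", {
  set.seed(52)
  for (i in 1:100) {
    s <- random_series(n_hours = 96, p_missing = 0.4, lo = 25, hi = 32)
    s$tw_c <- round(s$wbgt_c, 1)   # coarse values force ties
    s$unit_id <- "u"
    if (nrow(s) == 0) next
    got <- daily_max_tw(s)
    want <- oracle_daily_max(s$timestamp, s$tw_c)
    expect_equal(got$value, want$value)
    expect_equal(got$at, want$at)
  }
})

test_that("exceedance runs follow the bridging and termination rules of the worked traces", {
  mk <- function(hours, vals) data.frame(
    timestamp = as.POSIXct("2019-03-01 00:00:00", tz = TZ8) + 3600 * hours,
    wbgt_c = vals)
  # above at hours 1,2,3, missing 4, above at 5,6: one bridged run
  r <- exceedance_runs(mk(c(1, 2, 3, 5, 6), rep(31, 5)), threshold = 30)
  expect_equal(nrow(r), 1)
  expect_equal(r$duration_h, 6)
  expect_equal(r$n_records, 5L)
  expect_equal(r$n_bridged_gaps, 1L)
  # an observed below-threshold record splits the run even inside the window
  r2 <- exceedance_runs(mk(1:4, c(31, 31, 29, 31)), threshold = 30)
  expect_equal(nrow(r2), 2)
  expect_equal(r2$n_records, c(2L, 1L))
  # a 3-hour silence exceeds the 2-hour allowance
  r3 <- exceedance_runs(mk(c(1, 2, 5), c(31, 31, 31)), threshold = 30)
  expect_equal(nrow(r3), 2)
  # nothing above
  expect_equal(nrow(exceedance_runs(mk(1:3, c(25, 26, 24)), 30)), 0)
  # unsorted input is an error
  expect_error(exceedance_runs(mk(c(3, 1, 2), c(31, 31, 31)), 30), "sorted")
})

test_that("exceedance runs match the brute-force enumerator on random gappy series", {
  set.seed(53)
  for (i in 1:150) {
    s <- random_series(n_hours = 60, p_missing = runif(1, 0.1, 0.5))
    thr <- runif(1, 24, 34)
    got <- exceedance_runs(s, thr)
    want <- oracle_runs(s$timestamp, s$wbgt_c, thr)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$duration_h, want$duration_h)
      expect_equal(got$n_records, want$n_records)
      expect_equal(got$n_bridged_gaps, want$n_bridged_gaps)
    }
    # conservation: every above record sits in exactly one run
    expect_equal(sum(got$n_records), sum(s$wbgt_c >= thr))
  }
})

test_that("runs at a higher threshold nest inside runs at a lower one", {
  set.seed(54)
  for (i in 1:40) {
    s <- random_series(n_hours = 72, p_missing = 0.3)
    hi <- exceedance_runs(s, 31)
    lo <- exceedance_runs(s, 27)
    if (nrow(hi) == 0) next
    for (k in seq_len(nrow(hi))) {
      containing <- lo$start <= hi$start[k] & lo$end >= hi$end[k]
      expect_true(any(containing))
    }
  }
})

test_that("run-length histogram counts durations and cut-off exceedances", {
  runs <- data.frame(threshold = 30, duration_h = c(3, 3, 6),
                     n_records = c(3L, 3L, 5L))
  h <- run_length_histogram(runs, cutoffs = 5)
  expect_equal(h$histogram$n_runs[h$histogram$duration_h == 3], 2L)
  expect_equal(h$histogram$n_runs[h$histogram$duration_h == 6], 1L)
  expect_equal(h$over_cutoff$n_runs, 1L)
  expect_equal(sum(h$histogram$n_runs), nrow(runs))
  empty <- run_length_histogram(runs[0, ])
  expect_equal(nrow(empty$histogram), 0)
})

test_that("band frequencies partition records and report cumulative fractions", {
  vals <- c(24, 26, 29, 31, 34)
  bf <- band_frequencies(vals)
  expect_equal(bf$cumulative$fraction_ge, c(4, 3, 2, 1) / 5)
  expect_equal(sum(bf$bands$fraction), 1)
  expect_equal(bf$bands$n, rep(1L, 5))
  # all below the lowest threshold
  low <- band_frequencies(c(20, 22, 24))
  expect_equal(low$cumulative$fraction_ge, rep(0, 4))
  set.seed(55)
  rnd <- band_frequencies(runif(500, 15, 40))
  expect_equal(sum(rnd$bands$fraction), 1)
  expect_error(band_frequencies(vals, thresholds = c(a = 30, b = 25)),
               "increasing")
})

test_that("day/night split is an exhaustive disjoint partition on the local clock", {
  recs <- data.frame(
    timestamp = as.POSIXct("2019-03-01 00:00:00", tz = TZ8) + 3600 * 0:23,
    x = 1:24)
  parts <- day_night_split(recs)
  expect_equal(nrow(parts$day) + nrow(parts$night), 24)
  expect_equal(intersect(parts$day$x, parts$night$x), integer(0))
  expect_true(13 %in% parts$day$x)    # 12:00 record
  expect_true(4 %in% parts$night$x)   # 03:00 record
  expect_equal(sort(local_hour(parts$day$timestamp)), 6:17)
})

test_that("station comparison recovers exact and noisy injected offsets", {
  dates <- as.Date("2019-03-01") + 0:59
  situ <- data.frame(unit_id = "S01", date = dates, value = 30 + sin(1:60 / 5))
  # identical series: zero difference
  stat0 <- data.frame(unit_id = "971800", date = dates, value = situ$value)
  expect_equal(station_comparison(situ, stat0)$mean_difference, 0)
  # constant 1.3 offset
  stat1 <- transform(stat0, value = value - 1.3)
  cmp <- station_comparison(situ, stat1)
  expect_equal(cmp$mean_difference, 1.3)
  expect_equal(cmp$per_station$mean_difference, 1.3)
  # noisy offset: recovered within two standard errors
  set.seed(56)
  delta <- 0.9
  statn <- data.frame(unit_id = "971800", date = dates,
                      value = situ$value - delta + rnorm(60, 0, 0.4))
  cmpn <- station_comparison(situ, statn)
  se <- stats::sd(cmpn$differences$difference) / sqrt(60)
  expect_lt(abs(cmpn$mean_difference - delta), 2 * se)
  # disjoint dates are an error
  stat_off <- transform(stat0, date = date + 400)
  expect_error(station_comparison(situ, stat_off), "overlapping")
})

test_that("exposure summary aggregates fractions and longest runs coherently", {
  set.seed(57)
  recs <- data.frame(
    unit_id = rep(c("u1", "u2"), each = 72),
    timestamp = rep(as.POSIXct("2019-03-01 00:00:00", tz = TZ8) +
                      3600 * 0:71, 2),
    wbgt_c = 28 + 4 * sin(2 * pi * (0:143 %% 24 - 14) / 24) +
      rnorm(144, 0, 0.3)
  )
  es <- exposure_summary(recs)
  expect_equal(es$fractions$fraction_ge,
               sapply(c(25, 28, 30, 33), function(t) mean(recs$wbgt_c >= t)))
  expect_true(all(diff(es$fractions$fraction_ge) <= 0))
  if (nrow(es$runs) > 0) {
    expect_true(all(es$longest$longest_h >= 1))
  }
})
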