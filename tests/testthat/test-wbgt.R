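test_that("Bernard indoor WBGT collapses correctly for saturated air", {
  res <- bernard_indoor_wbgt(30, 30)
  expect_equal(res$natural_wet_bulb, 30, tolerance = 2e-3)
  expect_equal(res$wbgt, 30, tolerance = 2e-3)
  expect_equal(res$air_temperature, 30)
})

test_that("Bernard indoor WBGT lies between the wet bulb and the dry bulb", {
  res <- bernard_indoor_wbgt(34, 24)
  rh <- 100 * es_magnus(24) / es_magnus(34)
  tpwb <- thermodynamic_wet_bulb(34, rh)
  expect_gt(res$wbgt, tpwb)
  expect_lt(res$wbgt, 34)
})

test_that("Bernard indoor WBGT matches an independent step-by-step evaluation", {
  # hand evaluation of the cited relations at (32 degC, Td 26 degC, 1 m/s):
  # RH from dew point, psychrometric wet bulb by uniroot on the balance,
  # C(1 m/s) = 0.96, WBGT = 0.67 Tnwb + 0.33 Ta
  vp <- es_magnus(26)
  rh <- 100 * vp / es_magnus(32)
  tpwb <- stats::uniroot(
    function(tw) es_magnus(tw) - vp - 6.66e-4 * 1013 * (32 - tw),
    c(20, 32), tol = 1e-9)$root
  tnwb <- 32 - 0.96 * (32 - tpwb)
  res <- bernard_indoor_wbgt(32, 26)
  expect_equal(res$natural_wet_bulb, tnwb, tolerance = 1e-3)
  expect_equal(res$wbgt, 0.67 * tnwb + 0.33 * 32, tolerance = 1e-3)
})

test_that("Bernard rejects dew point above temperature and sub-range wind", {
  expect_error(bernard_indoor_wbgt(25, 26), "dew_point")
  expect_error(bernard_indoor_wbgt(30, 25, wind = 0.1), "wind")
})

test_that("Liljegren WBGT reduces to the air temperature without sun in saturated air", {
  for (wind in c(0.5, 2, 10)) {
    res <- liljegren_wbgt(30, 30, wind = wind, solar = 0)
    expect_equal(res$wbgt, 30, tolerance = 0.3)
  }
})

test_that("Liljegren globe approaches the air temperature in strong wind without sun", {
  res <- liljegren_wbgt(32, 22, wind = 10, solar = 0)
  expect_equal(res$globe_temperature, 32, tolerance = 0.2)
})

test_that("Liljegren WBGT responds monotonically to its drivers", {
  base <- list(t = 33, td = 24, wind = 2, solar = 700, zen = 30)
  w <- function(...) {
    a <- utils::modifyList(base, list(...))
    liljegren_wbgt(a$t, a$td, wind = a$wind, solar = a$solar,
                   zenith = a$zen)$wbgt
  }
  expect_lt(w(wind = 10), w(wind = 1))       # wind cools
  expect_gt(w(solar = 1000), w(solar = 100)) # sun heats
  expect_gt(w(t = 36), w(t = 30))            # warmer air
  expect_gt(w(td = 28), w(td = 18))          # moister air
  # randomized grid
  set.seed(7)
  for (i in 1:20) {
    t0 <- runif(1, 26, 38); td0 <- runif(1, 15, t0 - 2)
    s0 <- runif(1, 0, 900); v0 <- runif(1, 0.5, 8)
    expect_lte(w(t = t0, td = td0, solar = s0, wind = v0 + 2),
               w(t = t0, td = td0, solar = s0, wind = v0) + 1e-6)
    expect_lte(w(t = t0, td = td0, solar = s0, wind = v0),
               w(t = t0, td = td0, solar = s0 + 100, wind = v0) + 1e-6)
  }
})

test_that("Liljegren components satisfy the outdoor weighting identity exactly", {
  res <- liljegren_wbgt(c(30, 35), c(22, 26), wind = c(1, 4),
                        solar = c(800, 300), zenith = 25)
  expect_equal(res$wbgt,
               0.7 * res$natural_wet_bulb + 0.2 * res$globe_temperature +
                 0.1 * res$air_temperature)
  expect_true(all(res$globe_temperature > res$air_temperature))  # sun up
})

test_that("Liljegren treats night (zenith > 90) as zero solar load", {
  night <- liljegren_wbgt(28, 24, wind = 2, solar = 500, zenith = 120)
  dark <- liljegren_wbgt(28, 24, wind = 2, solar = 0, zenith = 90)
  expect_equal(night$wbgt, dark$wbgt, tolerance = 1e-6)
})

test_that("Liljegren rejects non-positive wind and negative solar", {
  expect_error(liljegren_wbgt(30, 20, wind = 0, solar = 100), "wind")
  expect_error(liljegren_wbgt(30, 20, wind = 1, solar = -5), "solar")
})

test_that("solar position gives a near-overhead equatorial noon and a night-time midnight", {
  noon <- as.POSIXct("2019-03-21 12:00:00", tz = TZ8)
  z <- solar_position(0, 120, noon)
  expect_lt(z, 5)
  expect_gt(solar_position(0, 120, noon + 12 * 3600), 90)
  expect_error(solar_position(0, 120, "2019-03-21 12:00"), "POSIXct")
})

test_that("solar position agrees with an independent ephemeris within half a degree", {
  stamps <- as.POSIXct(
    c("2018-11-15 08:00:00", "2018-12-21 12:00:00", "2019-01-05 16:00:00",
      "2019-02-10 10:30:00", "2019-03-01 12:00:00", "2019-03-21 06:30:00",
      "2019-04-15 14:00:00", "2019-05-31 11:00:00", "2019-05-01 17:30:00",
      "2019-02-28 13:15:00"), tz = TZ8)
  for (ts in seq_along(stamps)) {
    expect_lt(abs(solar_position(-5.13, 119.42, stamps[ts]) -
                    oracle_zenith(-5.13, 119.42, stamps[ts])), 0.5)
  }
})

test_that("scenario table defaults are the four study combinations", {
  sc <- default_scenarios()
  expect_setequal(paste(sc$solar, sc$wind),
                  c("0 10", "400 3", "1000 1", "1000 10"))
  expect_identical(sc$shaded, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("scenario files round-trip through JSON and YAML", {
  sc <- default_scenarios()
  fj <- file.path(tempdir(), "scen.json")
  jsonlite::write_json(sc, fj)
  expect_equal(as.data.frame(read_scenarios(fj)), as.data.frame(sc))
  fy <- file.path(tempdir(), "scen.yaml")
  yaml::write_yaml(lapply(seq_len(nrow(sc)), function(i) as.list(sc[i, ])), fy)
  expect_equal(as.data.frame(read_scenarios(fy)), as.data.frame(sc))
})

test_that("apply_scenarios orders shade below full sun and is deterministic", {
  recs <- data.frame(
    unit_id = "u1",
    timestamp = as.POSIXct("2019-03-01 13:00:00", tz = TZ8) + 3600 * 0:5,
    adj_temperature_c = c(31, 32.5, 33, 32, 30.5, 30),
    dew_point_c = c(25, 25.2, 25.1, 24.8, 24.9, 25)
  )
  out <- apply_scenarios(recs)
  w <- tidyr::pivot_wider(out[c("unit_id", "timestamp", "scenario", "wbgt_c")],
                          names_from = "scenario", values_from = "wbgt_c")
  expect_true(all(w$shade_wind10 < w$sun1000_wind1))
  expect_true(all(w$shade_wind10 < w$sun400_wind3))
  expect_true(all(w$sun400_wind3 < w$sun1000_wind1))
  expect_true(all(w$sun1000_wind10 < w$sun1000_wind1))
  out2 <- apply_scenarios(recs)
  expect_identical(out, out2)
  expect_warning(res <- apply_scenarios(recs[0, ]), "empty")
  expect_equal(nrow(res), 0)
})
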