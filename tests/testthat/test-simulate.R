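cfg_small <- function(...) {
  sim_config(seed = 7, n_settlements = 2, houses_per_settlement = 2,
             n_days = 3, ...)
}

test_that("the generator is deterministic and honours degenerate configs", {
  a <- simulate_network(cfg_small())
  b <- simulate_network(cfg_small())
  expect_identical(a$records, b$records)
  expect_identical(a$truth$unit_hours, b$truth$unit_hours)
  # zero noise, contamination and missingness: observations equal truth
  clean <- simulate_network(cfg_small(noise_sd = 0,
                                      missingness = list(block_rate = 0)))
  outdoor <- clean$records[clean$records$placement == "outdoor", ]
  truth_out <- clean$truth$unit_hours
  truth_out <- truth_out[truth_out$placement == "outdoor", ]
  m <- merge(outdoor, truth_out,
             by.x = c("logger_id", "timestamp"),
             by.y = c("unit_id", "timestamp"))
  expect_equal(m$temperature_c, m$t_true)
  expect_gt(nrow(m), 0)
})

test_that("invalid configurations are rejected before generation", {
  expect_error(sim_config(n_settlements = 0))
  expect_error(sim_config(house = list(amplitude_damping = 1.5)))
  expect_error(sim_config(contamination = list(fraction = 2)))
  expect_error(sim_config(wbgt = list(wind = 0)))
})

test_that("simulated houses invert the outdoor WBGT ordering between night and day", {
  clean <- simulate_network(cfg_small(noise_sd = 0,
                                      missingness = list(block_rate = 0)))
  uh <- clean$truth$unit_hours
  uh$hour <- as.integer(format(uh$timestamp, "%H", tz = local_timezone()))
  by_hour <- function(h, pl) {
    mean(uh$wbgt_true[uh$hour == h & uh$placement == pl])
  }
  expect_gt(by_hour(2, "house"), by_hour(2, "outdoor"))   # warmer at night
  expect_lt(by_hour(14, "house"), by_hour(14, "outdoor")) # cooler by day
})

test_that("the network structure matches the configured deployment", {
  cfg <- cfg_small()
  sim <- simulate_network(cfg)
  r <- sim$records
  expect_equal(length(unique(r$site_id)), 2)
  for (s in unique(r$site_id)) {
    rs <- r[r$site_id == s, ]
    expect_equal(length(unique(rs$logger_id[rs$placement == "outdoor"])),
                 cfg$outdoor_per_settlement)
    expect_equal(length(unique(rs$house_id[rs$placement == "house"])),
                 cfg$houses_per_settlement)
  }
  # outdoor loggers report RH, house loggers never do
  expect_true(all(!is.na(r$rh_pct[r$placement == "outdoor"])))
  expect_true(all(is.na(r$rh_pct[r$placement == "house"])))
  # two-hourly pair members emit even hours only
  two_hourly <- r[grepl("-L[4-6]$", r$logger_id), ]
  expect_true(all(as.integer(format(two_hourly$timestamp, "%H",
                                    tz = local_timezone())) %% 2 == 0))
})

test_that("contamination injects strictly positive daytime outdoor spikes and logs them", {
  cfg <- cfg_small(missingness = list(block_rate = 0))
  sim <- simulate_network(cfg)
  cont <- inject_contamination(sim$records, cfg)
  expect_true(all(cont$log$magnitude > 0))
  changed <- cont$records$temperature_c != sim$records$temperature_c
  expect_equal(sum(changed), nrow(cont$log))
  expect_true(all(cont$records$placement[changed] == "outdoor"))
  h <- as.integer(format(cont$records$timestamp[changed], "%H",
                         tz = local_timezone()))
  expect_true(all(h >= 6 & h < 18))
  # zero fraction leaves everything untouched
  none <- inject_contamination(sim$records,
                               cfg_small(contamination = list(fraction = 0)))
  expect_identical(none$records, sim$records)
  expect_equal(nrow(none$log), 0)
  # a fraction beyond the quantile headroom warns
  expect_warning(
    inject_contamination(sim$records,
                         cfg_small(contamination = list(fraction = 0.2))),
    "headroom")
})

test_that("noise-free zero-offset stations reproduce the settlement-mean truth wet bulb", {
  cfg <- cfg_small(noise_sd = 0,
                   missingness = list(block_rate = 0),
                   station = list(offset = 0, noise_sd = 0,
                                  qc_fail_rate = 0, cadence = 2L))
  sim <- simulate_network(cfg)
  st <- simulate_station(cfg, sim$truth)
  expect_equal(nrow(st$log), 0)
  # settlement-mean truth at station cadence
  uh <- sim$truth$unit_hours
  uh <- uh[uh$placement == "outdoor", ]
  base <- aggregate(cbind(t_true, vp_true) ~ timestamp,
                    data = unique(uh[c("site_id", "timestamp", "t_true",
                                       "vp_true")]), FUN = mean)
  tw <- station_tw(st$records[st$records$station_id == "971800", ])
  m <- merge(tw, base, by.x = "timestamp", by.y = "timestamp")
  rh_truth <- pmin(100, 100 * m$vp_true / es_magnus(round(m$t_true, 1)))
  tw_truth <- stull_wet_bulb(round(m$t_true, 1), rh_truth)
  # station temperatures are rounded to ISD tenths; dew point consistency
  # keeps the wet bulb within that resolution
  expect_equal(m$tw_c, tw_truth, tolerance = 0.06)
  got <- daily_max_tw(tw)
  want <- oracle_daily_max(m$timestamp, tw_truth)
  expect_equal(got$value, want$value, tolerance = 0.06)
})

test_that("station QC failures are exactly the logged records", {
  cfg <- cfg_small(station = list(qc_fail_rate = 0.1))
  sim <- simulate_network(cfg)
  st <- simulate_station(cfg, sim$truth)
  failed <- st$records[st$records$temperature_qc != "1",
                       c("station_id", "timestamp_utc")]
  expect_equal(nrow(failed), nrow(st$log))
  expect_equal(failed$timestamp_utc, st$log$timestamp_utc)
  filtered <- qc_filter(st$records)
  expect_equal(sum(filtered$report$n_removed), nrow(st$log))
})

test_that("fixtures round-trip through the CSV and ISD writers", {
  cfg <- cfg_small()
  sim <- simulate_network(cfg)
  st <- simulate_station(cfg, sim$truth)
  out <- file.path(tempdir(), "fixtures-test")
  files <- write_fixtures(sim$records, st$records, out,
                          truth = sim$truth, config = cfg)
  back <- read_logger_csv(files[["loggers"]])
  expect_equal(nrow(back), nrow(sim$records))
  expect_equal(back$temperature_c, sim$records$temperature_c,
               tolerance = 1e-12)
  isd <- read_isd(files[["971800"]])
  orig <- st$records[st$records$station_id == "971800", ]
  expect_equal(isd$temperature_c, orig$temperature_c)
  expect_equal(isd$timestamp_utc, orig$timestamp_utc)
  cfg_back <- jsonlite::fromJSON(file.path(out, "config.json"))
  expect_equal(cfg_back$seed, cfg$seed)
})
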