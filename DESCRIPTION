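Package: heatexposure
Title: Heat Stress Exposure Analysis for In Situ Urban Sensor Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes temperature and humidity records from dense urban
    sensor networks into occupational heat stress metrics. Implements the
    Stull closed-form wet bulb temperature with an independent iterative
    thermodynamic solver, Bernard indoor and Liljegren outdoor wet bulb
    globe temperature (WBGT) models, a percentile-based correction for
    solar inflation of shielded loggers, settlement-level vapour pressure
    homogenization, gap-tolerant exceedance runs over ISO 7243 activity
    thresholds, weather-station (Integrated Surface Database) ingestion
    and comparison, and a seeded synthetic network generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
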