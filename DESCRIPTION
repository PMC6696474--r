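Package: heatwarn
Title: Heat-Stress Indices and Heat-Warning Threshold Calibration and
    Verification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes nine direct thermal (heat-stress) indices from hourly
    station weather (heat index, wet-bulb temperature, wet bulb globe
    temperature in shade and sun, simplified WBGT, apparent temperature,
    effective temperature, humidex, discomfort index), calibrates warning
    thresholds for alternative indices against an official heat-index rule
    by site-specific frequency matching or region-wide pooled-window
    averaging, detects warning days and multi-day warning periods, and
    quantifies agreement between warning systems with single-day match
    percentages, per-duration-category hit rates and quality-of-hit
    statistics.  Includes a seeded synthetic hourly weather generator with
    diurnal and seasonal cycles, temperature-humidity anticorrelation and
    multi-day heat episodes, so the whole pipeline is testable without
    station archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
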