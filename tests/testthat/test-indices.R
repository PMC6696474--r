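# Index closed forms against independently computed frozen values and the
# qualitative physics each formula must respect.

test_that("heat index obeys its 80 F lower bound and the NWS regression", {
  expect_identical(heat_index(25, 50), 0)         # 77 F, below the bound
  expect_equal(heat_index(35, 60), 113.0903083, tolerance = 1e-7)
  expect_gt(heat_index(33, 70), heat_index(33, 40))  # humidity raises hi
  expect_gte(heat_index(33, 40), 80)
})

test_that("heat index adjustment terms apply in their validity ranges", {
  # dry adjustment lowers hi relative to the bare regression
  t_f <- celsius_to_fahrenheit(35)
  bare <- -42.379 + 2.04901523 * t_f + 10.14333127 * 10 -
    0.22475541 * t_f * 10 - 6.83783e-3 * t_f^2 - 5.481717e-2 * 100 +
    1.22874e-3 * t_f^2 * 10 + 8.5282e-4 * t_f * 100 - 1.99e-6 * t_f^2 * 100
  expect_lt(heat_index(35, 10), bare)
  # monotone non-decreasing in temperature at fixed humidity
  ta <- seq(27, 42, by = 0.5)
  expect_true(all(diff(heat_index(ta, 60)) >= 0))
})

test_that("Stull wet bulb matches its closed form and flags out-of-envelope input", {
  expect_equal(as.numeric(wet_bulb_temperature(30, 40)),
               20.44920202182018, tolerance = 1e-10)
  expect_gt(as.numeric(wet_bulb_temperature(35, 80)),
            as.numeric(wet_bulb_temperature(30, 80)))
  expect_warning(w <- wet_bulb_temperature(30, 3), "envelope")
  expect_true(any(attr(w, "out_of_range")))
  expect_silent(wet_bulb_temperature(30, 3, warn = FALSE))
})

test_that("shade WBGT reduces to ta at saturation and matches a brentq oracle", {
  expect_equal(wbgt_shade(30, 30), 30, tolerance = 1e-3)
  # frozen: 0.7 * (32 - 0.96*(32 - Tpwb)) + 0.3*32 with Tpwb from brentq
  expect_equal(wbgt_shade(32, 20), 26.314438899858267, tolerance = 2e-3)
  # moister air gives a higher shade WBGT
  td <- seq(10, 29, by = 1)
  expect_true(all(diff(wbgt_shade(rep(30, length(td)), td)) > 0))
  expect_lt(wbgt_shade(30, 15), 30)  # below ta for unsaturated air
})

test_that("shade WBGT wet bulb agrees with an independent dense-grid root scan", {
  # independent oracle: locate the Bernard balance root by scanning a
  # 0.0005-degree grid instead of the package's bisection
  es <- function(t) 6.105 * exp(17.27 * t / (237.7 + t))
  for (case in list(c(28, 14), c(33, 25), c(38, 20))) {
    ta <- case[1]; td <- case[2]
    grid <- seq(td, ta, by = 5e-4)
    ed <- es(td)
    f <- 1556 * ed - 1.484 * ed * grid - 1556 * es(grid) +
      1.484 * es(grid) * grid + 1010 * (ta - grid)
    tw_scan <- grid[which.min(abs(f))]
    expect_equal(psychrometric_wet_bulb(ta, td), tw_scan, tolerance = 3e-3)
  }
})

test_that("simplified WBGT is the published affine form", {
  # zero humidity: affine in ta with the published temperature coefficient
  ta <- seq(20, 40, by = 5)
  expect_equal(simplified_wbgt(ta, 0), 0.567 * ta + 3.94)
  expect_equal(simplified_wbgt(30, 60), 30.921312666383603,
               tolerance = 1e-10)
  expect_gt(simplified_wbgt(30, 80), simplified_wbgt(30, 40))
})

test_that("apparent temperature cools with wind and warms with humidity", {
  expect_lt(apparent_temperature(30, 50, 5), apparent_temperature(30, 50, 0))
  expect_equal(apparent_temperature(30, 60, 1), 33.6728579641389,
               tolerance = 1e-10)
  expect_gt(apparent_temperature(32, 70, 1), apparent_temperature(32, 30, 1))
})

test_that("effective temperature anchors at skin temperature and matches its form", {
  # at ta = 37 only the humidity correction term remains
  expect_equal(effective_temperature(37, 50, 1), 37 - 0.29 * 37 * 0.5,
               tolerance = 1e-12)
  expect_equal(effective_temperature(30, 50, 1), 25.094322994944662,
               tolerance = 1e-10)
  # humidity raises ET throughout the warm regime (brute-force sign check)
  for (ta in seq(25, 40, by = 1)) {
    expect_gt(effective_temperature(ta, 90, 1),
              effective_temperature(ta, 30, 1))
  }
})

test_that("humidex equals ta at 10 hPa vapor pressure and errors at rh 0", {
  # rh chosen so the dew-point vapor pressure is exactly 10 hPa at 30 C
  rh10 <- 100 * 10 / saturation_vapor_pressure(30)
  expect_equal(humidex(30, rh10), 30, tolerance = 1e-9)
  expect_equal(humidex(30, 70), 40.888362724017234, tolerance = 1e-10)
  expect_gt(humidex(30, 80), humidex(30, 50))
  expect_error(humidex(30, 0), "undefined")
})

test_that("discomfort index variants behave as documented", {
  # wet-bulb variant: saturated limit collapses to ta within the Stull
  # formula's accuracy envelope
  expect_equal(discomfort_index(30, 100), 30, tolerance = 0.5)
  expect_equal(discomfort_index(30, 60), 26.997759306159722,
               tolerance = 1e-10)
  expect_gt(discomfort_index(35, 50), discomfort_index(30, 50))
  # Thom variant is its closed form
  expect_equal(discomfort_index(30, 60, variant = "thom"),
               30 - 0.55 * 0.4 * (30 - 14.5))
})

test_that("every index is monotone non-decreasing in temperature", {
  ta <- seq(20, 40, by = 1)
  curves <- list(
    hi = heat_index(ta, 60),
    wbt = as.numeric(wet_bulb_temperature(ta, 60)),
    wbgt.shade = wbgt_shade(ta, dew_point(ta, 60)),
    wbgt.sun = wbgt_sun(ta, dew_point(ta, 60), 1.5, 600, 30),
    swbgt = simplified_wbgt(ta, 60),
    apparentTemp = apparent_temperature(ta, 60, 1),
    effectiveTemp = effective_temperature(ta, 60, 1),
    humidex = humidex(ta, 60),
    discomInd = discomfort_index(ta, 60)
  )
  for (nm in names(curves)) {
    expect_true(all(diff(curves[[nm]]) >= -1e-9),
                info = paste("monotonicity in ta for", nm))
  }
})

test_that("compute_indices returns validated long output", {
  ser <- generate_station(climate_spec(seed = 7), years = 1)
  ser <- ser[1:240, ]
  out <- compute_indices(ser, indices = c("hi", "swbgt", "wbt"))
  expect_setequal(unique(out$index_name), c("hi", "swbgt", "wbt"))
  expect_equal(nrow(out), 3 * nrow(ser))
  expect_equal(unique(out$unit[out$index_name == "hi"]), "degF")
  expect_equal(unique(out$unit[out$index_name == "swbgt"]), "degC")
  expect_error(compute_indices(ser, indices = "wbgt.sun"), "latitude")
  expect_error(compute_indices(ser, indices = "nope"), "unknown")
})
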