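# Warning-agreement metrics: single-day matches, overlap pairs, hit rates,
# quality of hits, the orchestrated report, and the response-surface
# sensitivity analysis.

jun <- function(d, year = 2017) as.Date(sprintf("%d-06-01", year)) + d - 1

test_that("single-day match reproduces the ten-day worked example", {
  off <- jun(1:10)
  alt <- c(jun(c(3, 7)), jun(40:47))          # 10 alt days, 2 coincide
  expect_equal(single_day_match(off, alt), 20)
  expect_equal(single_day_match(off, off), 100)
  expect_equal(single_day_match(off, jun(40:49)), 0)
  expect_error(single_day_match(as.Date(character()), alt), "undefined")
})

test_that("overlap pairs carry exact shared-day counts", {
  off <- warning_periods(jun(2:5))            # Jun 2-5, one 4-day period
  alt <- warning_periods(jun(5:7))            # Jun 5-7
  p <- overlap_pairs(off, alt)
  expect_equal(nrow(p), 1)
  expect_equal(p$overlap_days, 1L)
  expect_equal(p$official_length, 4L)

  expect_equal(nrow(overlap_pairs(off, warning_periods(jun(20:23)))), 0)

  off10 <- warning_periods(jun(1:10))
  alt2 <- warning_periods(jun(c(2:4, 7:9)))
  p2 <- overlap_pairs(off10, alt2)
  expect_equal(nrow(p2), 2)
  expect_equal(sort(p2$overlap_days), c(3L, 3L))
})

test_that("hit rate matches the worked examples including the 200% case", {
  off <- warning_periods(jun(2:5))
  alt <- warning_periods(jun(5:7))
  hr <- hit_rate(overlap_pairs(off, alt), off, "4")
  expect_equal(hr$hit_rate, 100)
  expect_equal(hr$n_official, 1L)

  # one official 5+ period hit by two alternative periods -> 200 %
  off5 <- warning_periods(jun(1:8))
  alt5 <- warning_periods(jun(c(1:3, 6:8)))
  hr5 <- hit_rate(overlap_pairs(off5, alt5), off5, "5+")
  expect_equal(hr5$hit_rate, 200)
  expect_equal(hr5$hit_rate_captured, 100)    # captured-official convention

  # missed official period
  hr0 <- hit_rate(overlap_pairs(off, warning_periods(jun(20:23))), off, "4")
  expect_equal(hr0$hit_rate, 0)
  # no official events in the category: the asterisk marker
  hrNA <- hit_rate(overlap_pairs(off, alt), off, "3")
  expect_true(hrNA$no_official_events)
  expect_true(is.na(hrNA$hit_rate))
})

test_that("quality of hits matches the worked examples", {
  off <- warning_periods(jun(2:5))
  alt <- warning_periods(jun(5:7))
  expect_equal(quality_of_hits(overlap_pairs(off, alt), "4"), 25)
  expect_equal(quality_of_hits(overlap_pairs(off, off), "4"), 100)

  # two pairs on one official 10-day period with overlaps 3 and 4 days
  off10 <- warning_periods(jun(1:10))
  alt2 <- warning_periods(jun(c(1:3, 6:9)))
  expect_equal(quality_of_hits(overlap_pairs(off10, alt2), "5+"), 35)
  # missing category reported as NA, not 0
  expect_true(is.na(quality_of_hits(overlap_pairs(off10, alt2), "3")))
})

test_that("hit rate and quality equal brute-force enumeration on random instances", {
  set.seed(99)
  for (rep in 1:60) {
    off <- random_periods(p = runif(1, 0.2, 0.6))
    alt <- random_periods(p = runif(1, 0.2, 0.6))
    pairs <- overlap_pairs(off, alt)
    for (cc in c("3", "4", "5+")) {
      bf <- brute_force_match(off, alt, cc)
      hr <- hit_rate(pairs, off, cc)
      expect_equal(hr$hit_rate, bf$hit_rate, info = paste(rep, cc))
      expect_equal(quality_of_hits(pairs, cc), bf$quality,
                   info = paste(rep, cc))
    }
  }
})

test_that("per-pair quality is always in (0, 100]", {
  set.seed(7)
  for (rep in 1:20) {
    p <- overlap_pairs(random_periods(0.5), random_periods(0.5))
    if (nrow(p)) {
      expect_true(all(p$quality > 0 & p$quality <= 100))
    }
  }
})

test_that("a system matched against itself scores 100 everywhere", {
  set.seed(13)
  vals_f <- c(80, 80, 92, 93, 95, 80, 91, 94, 95, 96, 97, 80, 80, 91.5,
              95, 96, 80, runif(20, 80, 96))
  d <- make_daily(vals_f, index = "hi")
  rep_self <- build_match_report(d, d, alt_threshold = 90, cutoff_f = 90)
  expect_equal(rep_self$single_day_match, 100)
  expect_equal(rep_self$n_official_days, rep_self$n_alt_days)
  expect_equal(rep_self$false_alarms, 0L)
  for (cc in names(rep_self$categories)) {
    ci <- rep_self$categories[[cc]]
    if (!ci$no_official_events) {
      expect_equal(ci$hit_rate, 100)
      expect_equal(ci$mean_quality, 100)
    }
  }
})

test_that("lowering the alternative threshold never lowers the single-day match", {
  daily <- network_daily_fixture(n_stations = 3, years = 4, master_seed = 9)
  st <- unique(daily$station_id)[1]
  hi_d <- daily[daily$index_name == "hi" & daily$station_id == st, ]
  sw_d <- daily[daily$index_name == "swbgt" & daily$station_id == st, ]
  off <- official_warning_days(hi_d, 90)
  expect_gt(length(off), 0)
  thr0 <- as.numeric(site_specific_threshold(sw_d$value, length(off)))
  matches <- vapply(c(thr0 + 0.5, thr0, thr0 - 0.5, thr0 - 1.5),
                    function(t) single_day_match(off, warning_days(sw_d, t)),
                    numeric(1))
  expect_true(all(diff(matches) >= 0))
})

test_that("single-day match is symmetric when both systems flag equally many days", {
  daily <- network_daily_fixture(n_stations = 3, years = 4, master_seed = 9)
  st <- unique(daily$station_id)[2]
  hi_d <- daily[daily$index_name == "hi" & daily$station_id == st, ]
  sw_d <- daily[daily$index_name == "swbgt" & daily$station_id == st, ]
  off <- official_warning_days(hi_d, 90)
  expect_gt(length(off), 0)
  thr <- site_specific_threshold(sw_d$value, length(off))
  alt <- warning_days(sw_d, as.numeric(thr))
  expect_equal(length(alt), length(off))  # tie-free calibration
  expect_equal(single_day_match(off, alt), single_day_match(alt, off))
})

test_that("match report on a constructed overlap structure equals brute force", {
  # official: Jun 1-3 (3), Jun 10-13 (4), Jun 20-27 (5+)
  hi_vals <- rep(80, 40)
  hi_vals[c(1:3, 10:13, 20:27)] <- 95
  # alternative: Jun 2-4, Jun 12-15, Jun 19-21, Jun 24-26
  alt_vals <- rep(20, 40)
  alt_vals[c(2:4, 12:15, 19:21, 24:26)] <- 30
  rep1 <- build_match_report(make_daily(hi_vals, index = "hi"),
                             make_daily(alt_vals, index = "swbgt"),
                             alt_threshold = 25)
  off_p <- warning_periods(jun(c(1:3, 10:13, 20:27)))
  alt_p <- warning_periods(jun(c(2:4, 12:15, 19:21, 24:26)))
  for (cc in c("3", "4", "5+")) {
    bf <- brute_force_match(off_p, alt_p, cc)
    expect_equal(rep1$categories[[cc]]$hit_rate, bf$hit_rate, info = cc)
    expect_equal(rep1$categories[[cc]]$mean_quality, bf$quality, info = cc)
  }
  expect_equal(rep1$single_day_match,
               100 * length(intersect(jun(c(1:3, 10:13, 20:27)),
                                      jun(c(2:4, 12:15, 19:21, 24:26)))) /
                 15)
  expect_equal(rep1$false_alarms, 0L)
})

test_that("response surface returns the analytic slope for affine indices", {
  rs <- response_surface("swbgt", list(ta = 30, rh = 50, ws = 1, rad = 0),
                         "rh", seq(20, 100, by = 5))
  expect_equal(attr(rs, "slope"),
               0.393 * saturation_vapor_pressure(30) / 100,
               tolerance = 1e-10)
  # temperature slope of apparentTemp: 1 + 0.33 * rh/100 * des/dta
  h <- 1e-5
  des <- (saturation_vapor_pressure(30 + h) -
            saturation_vapor_pressure(30 - h)) / (2 * h)
  rs_at <- response_surface("apparentTemp",
                            list(ta = 30, rh = 50, ws = 1, rad = 0),
                            "ta", seq(29.9, 30.1, by = 0.01))
  expect_equal(attr(rs_at, "slope"), 1 + 0.33 * 0.5 * des, tolerance = 1e-4)
})

test_that("response surface rejects inputs the index does not use", {
  expect_error(response_surface("wbt", list(ta = 30, rh = 50, ws = 1),
                                "ws", 0:5), "does not use")
  expect_error(response_surface("swbgt", list(ta = 30, rh = 50),
                                "rad", c(0, 100)), "does not use")
  expect_error(response_surface("nope", list(ta = 30, rh = 50), "rh", 1:2),
               "unknown")
})
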