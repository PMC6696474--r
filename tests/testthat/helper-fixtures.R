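# Shared fixtures and independent oracles for the suite.  The expensive
# multi-station daily-maximum fixture is built once per run and cached.

.fixtures <- new.env(parent = emptyenv())

# Long daily-maximum data frame for a homogeneous synthetic network:
# `n_stations` identical climate specs (independent substreams), all nine
# indices, daily maxima in local time.
network_daily_fixture <- function(n_stations = 20, years = 10,
                                  master_seed = 1) {
  key <- sprintf("net_%d_%d_%d", n_stations, years, master_seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  specs <- lapply(seq_len(n_stations), function(i) {
    climate_spec(station_id = sprintf("SYN%02d", i))
  })
  series <- generate_network(specs, years, master_seed = master_seed)
  daily <- do.call(rbind, lapply(names(series), function(st) {
    hourly <- compute_indices(series[[st]], lat = 47, lon = 8)
    daily_maximum(hourly)
  }))
  .fixtures[[key]] <- daily
  daily
}

# small hourly index data frame for events tests
make_hourly <- function(values, start = "2017-06-01 00:00:00",
                        station = "X", index = "ta") {
  ts <- as.POSIXct(start, tz = "UTC") + 3600 * (seq_along(values) - 1)
  data.frame(station_id = station, timestamp = ts, index_name = index,
             value = values, stringsAsFactors = FALSE)
}

# daily series data frame from a value vector
make_daily <- function(values, start = "2017-06-01", station = "X",
                       index = "idx") {
  data.frame(station_id = station, index_name = index,
             date = as.Date(start) + seq_along(values) - 1,
             value = values, stringsAsFactors = FALSE)
}

# Brute-force event-matching oracle: day-by-day enumeration, independent
# of overlap_pairs()/hit_rate()/quality_of_hits().
brute_force_match <- function(off_periods, alt_periods, category) {
  keep <- which(off_periods$category == category)
  n_off <- length(keep)
  if (n_off == 0) return(list(hit_rate = NA_real_, quality = NA_real_))
  alt_hits <- logical(nrow(alt_periods))
  qualities <- numeric(0)
  for (i in keep) {
    off_days <- seq(off_periods$start[i], off_periods$end[i], by = "day")
    for (j in seq_len(nrow(alt_periods))) {
      alt_days <- seq(alt_periods$start[j], alt_periods$end[j], by = "day")
      ov <- length(intersect(off_days, alt_days))
      if (ov >= 1) {
        alt_hits[j] <- TRUE
        qualities <- c(qualities, 100 * ov / length(off_days))
      }
    }
  }
  list(
    hit_rate = 100 * sum(alt_hits) / n_off,
    quality = if (length(qualities)) mean(qualities) else NA_real_
  )
}

# random warning-day set on a 60-day window -> periods
random_periods <- function(p = 0.35, n_days = 60,
                           origin = as.Date("2010-06-01")) {
  days <- origin + which(stats::runif(n_days) < p) - 1
  warning_periods(days, 3)
}
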