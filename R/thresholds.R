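# Threshold calibration for alternative indices against the official
# heat-index rule.  Two procedures: (1) site-specific frequency matching,
# which forces the alternative index to flag exactly as many warning days
# as the official system at each station; (2) region-wide pooled-window
# averaging, which averages the alternative-index values on days whose
# heat index falls strictly inside a window around the official cutoff,
# pooled over all stations.  A spatial mean/sd summary of the
# site-specific thresholds is the third, descriptive mode.

#' Official warning days from a daily heat-index series
#'
#' Dates whose daily-maximum heat index strictly exceeds the official
#' cutoff (90 F for danger level 3; 93 F for level 4).
#'
#' @param daily_hi Data frame with `date` and `value` (daily-maximum heat
#'   index in degrees Fahrenheit).
#' @param cutoff_f Cutoff in degrees Fahrenheit (default 90).
#' @return Sorted vector of `Date`s.
#' @export
official_warning_days <- function(daily_hi, cutoff_f = 90) {
  warning_days(daily_hi, cutoff_f)
}

#' Site-specific threshold by frequency matching
#'
#' Sorts the station's daily index values in ascending order and returns
#' the value followed by exactly `n_official` larger values, i.e. the
#' (N - n_official)-th ascending order statistic.  In the tie-free case
#' exactly `n_official` days then strictly exceed the returned threshold,
#' so the alternative index reproduces the official warning-day count at
#' that station.  With duplicated values an exact count may be impossible;
#' the order statistic is still returned and the achieved count reported
#' via the `"achieved_count"` attribute.
#'
#' @param values Numeric vector of daily index values (one station, one
#'   index; NAs dropped).
#' @param n_official Number of official warning days at the station.
#' @return Threshold (same unit as `values`) with attribute
#'   `achieved_count`, the number of values strictly above it.
#' @export
#' @examples
#' site_specific_threshold(c(1, 2, 3, 4, 5), 2)  # 3
site_specific_threshold <- function(values, n_official) {
  values <- values[!is.na(values)]
  n <- length(values)
  stopifnot(n_official >= 0)
  if (n_official >= n) {
    stop("cannot place a threshold: n_official (", n_official,
         ") must be smaller than the number of days (", n, ")",
         call. = FALSE)
  }
  s <- sort(values)
  thr <- s[n - n_official]
  structure(thr, achieved_count = sum(values > thr))
}

#' Region-wide threshold by pooled-window averaging
#'
#' Pools daily (index, heat index) pairs across all stations and averages
#' the index values on days whose heat index lies strictly inside the
#' window (default 88 F to 92 F around the official 90 F cutoff).  The
#' result is a single threshold shared by the whole network.
#'
#' @param index_values Daily index values (degrees Celsius), pooled over
#'   stations and days.
#' @param hi_values Matching daily heat-index values (degrees Fahrenheit).
#' @param window Length-2 numeric, the open window in degrees Fahrenheit
#'   (default `c(88, 92)`); both bounds strict.
#' @return Threshold in the index's unit, with attribute `n_support`, the
#'   number of pooled days inside the window.
#' @export
#' @examples
#' region_wide_threshold(c(20, 22, 24, 30), c(85, 89, 91, 95))  # 23
region_wide_threshold <- function(index_values, hi_values,
                                  window = c(88, 92)) {
  stopifnot(length(index_values) == length(hi_values),
            length(window) == 2, window[1] < window[2])
  inside <- !is.na(hi_values) & !is.na(index_values) &
    hi_values > window[1] & hi_values < window[2]
  if (!any(inside)) {
    stop("no pooled days with heat index strictly inside the window (",
         window[1], ", ", window[2], ") F", call. = FALSE)
  }
  structure(mean(index_values[inside]), n_support = sum(inside))
}

#' Spatial mean and standard deviation of site-specific thresholds
#'
#' Descriptive network summary of the site-specific thresholds of one
#' index.  The standard deviation uses the population convention
#' (divide by n) by default; with n around 28 stations the difference from
#' the sample convention is small either way.
#'
#' @param site_thresholds Named numeric vector, station id -> threshold.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return List with `mean` and `sd` (degrees Celsius).
#' @export
spatial_mean_threshold <- function(site_thresholds,
                                   sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- as.numeric(site_thresholds)
  x <- x[!is.na(x)]
  if (length(x) < 2) {
    stop("spatial spread is undefined for fewer than 2 stations",
         call. = FALSE)
  }
  s <- stats::sd(x)
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  list(mean = mean(x), sd = s)
}

#' Calibrate thresholds for a set of stations and indices
#'
#' Convenience driver over daily-maximum series: derives, for each
#' requested index, site-specific thresholds (frequency matching against
#' the official heat-index warning-day count per station), the region-wide
#' pooled-window threshold, and the spatial mean/sd of the site-specific
#' values.
#'
#' @param daily Long daily-maximum data frame from [daily_maximum()]
#'   covering the index `"hi"` plus the alternative indices.
#' @param indices Indices to calibrate (default: all non-hi indices
#'   present).
#' @param cutoff_f Official cutoff in degrees Fahrenheit.
#' @param window Pooling window in degrees Fahrenheit.
#' @param sd_type Passed to [spatial_mean_threshold()].
#' @return Data frame `index_name`, `mode`, `station_id`, `threshold`,
#'   `spatial_sd` (`mode` one of `site_specific`, `region_wide`,
#'   `spatial_mean`; `station_id` is NA for network-wide rows).
#' @export
calibrate_thresholds <- function(daily, indices = NULL, cutoff_f = 90,
                                 window = c(88, 92),
                                 sd_type = "population") {
  if (!any(daily$index_name == "hi")) {
    stop("daily series must include the official index 'hi'",
         call. = FALSE)
  }
  if (is.null(indices)) {
    indices <- setdiff(unique(daily$index_name), "hi")
  }
  stations <- sort(unique(daily$station_id))
  hi_daily <- daily[daily$index_name == "hi", , drop = FALSE]

  rows <- list()
  for (ix in indices) {
    ix_daily <- daily[daily$index_name == ix, , drop = FALSE]
    site_thr <- vapply(stations, function(st) {
      hs <- hi_daily[hi_daily$station_id == st, , drop = FALSE]
      xs <- ix_daily[ix_daily$station_id == st, , drop = FALSE]
      # align on common dates so both systems see the same day set
      common <- as.Date(intersect(hs$date, xs$date), origin = "1970-01-01")
      hs <- hs[hs$date %in% common, , drop = FALSE]
      xs <- xs[xs$date %in% common, , drop = FALSE]
      n_off <- length(official_warning_days(hs, cutoff_f))
      as.numeric(site_specific_threshold(xs$value, n_off))
    }, numeric(1))
    names(site_thr) <- stations

    # pooled pairs across all stations, aligned by station and date
    key_hi <- paste(hi_daily$station_id, hi_daily$date)
    key_ix <- paste(ix_daily$station_id, ix_daily$date)
    m <- match(key_ix, key_hi)
    paired <- !is.na(m)
    region <- as.numeric(region_wide_threshold(
      ix_daily$value[paired], hi_daily$value[m[paired]], window))
    spat <- spatial_mean_threshold(site_thr, sd_type)

    rows[[ix]] <- rbind(
      data.frame(index_name = ix, mode = "site_specific",
                 station_id = stations, threshold = unname(site_thr),
                 spatial_sd = NA_real_, stringsAsFactors = FALSE),
      data.frame(index_name = ix, mode = "region_wide",
                 station_id = NA_character_, threshold = region,
                 spatial_sd = NA_real_, stringsAsFactors = FALSE),
      data.frame(index_name = ix, mode = "spatial_mean",
                 station_id = NA_character_, threshold = spat$mean,
                 spatial_sd = spat$sd, stringsAsFactors = FALSE)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
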