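# Daily aggregation and warning-event machinery: hourly index values are
# reduced to daily maxima, daily maxima are screened against a threshold,
# and runs of consecutive warning days become warning periods with the
# 3-day / 4-day / 5-plus-day duration categories.

#' Daily maxima of an hourly index series
#'
#' Assigns each hourly value to a calendar day in local standard time
#' (a fixed UTC offset; no daylight-saving arithmetic, since daily maxima
#' are afternoon events and insensitive to a one-hour shift) and takes the
#' maximum per day.  Days with fewer than `min_hours` of the 24 hourly
#' values present are dropped: a short day cannot be trusted to contain
#' the true maximum, and a dropped day deliberately breaks runs of
#' consecutive warning days.
#'
#' @param hourly Data frame with columns `station_id`, `timestamp`
#'   (POSIXct, UTC), `index_name`, `value`, and optionally `unit`.
#' @param tz_offset_hours Fixed local-time offset from UTC in hours
#'   (default 1, central-European standard time).
#' @param min_hours Minimum number of non-missing hourly values a day must
#'   have to be retained (default 18 of 24).
#' @return Data frame `station_id`, `index_name`, `date` (Date), `value`
#'   (daily maximum), `n_hours`, sorted by date, plus `unit` if present in
#'   the input.
#' @export
daily_maximum <- function(hourly, tz_offset_hours = 1, min_hours = 18L) {
  stopifnot(min_hours >= 1, min_hours <= 24)
  ok <- !is.na(hourly$value)
  h <- hourly[ok, , drop = FALSE]
  if (nrow(h) == 0) {
    out <- data.frame(station_id = character(), index_name = character(),
                      date = as.Date(character()), value = numeric(),
                      n_hours = integer(), stringsAsFactors = FALSE)
    return(out)
  }
  local_day <- as.Date(h$timestamp + tz_offset_hours * 3600, tz = "UTC")
  key <- paste(h$station_id, h$index_name, local_day, sep = "\r")
  mx <- tapply(h$value, key, max)
  cnt <- tapply(h$value, key, length)
  parts <- do.call(rbind, strsplit(names(mx), "\r", fixed = TRUE))
  out <- data.frame(
    station_id = parts[, 1],
    index_name = parts[, 2],
    date = as.Date(parts[, 3]),
    value = as.numeric(mx),
    n_hours = as.integer(cnt),
    stringsAsFactors = FALSE
  )
  if (!is.null(hourly$unit)) {
    u <- unique(h[, c("station_id", "index_name", "unit")])
    out$unit <- u$unit[match(paste(out$station_id, out$index_name),
                             paste(u$station_id, u$index_name))]
  }
  out <- out[out$n_hours >= min_hours, , drop = FALSE]
  out <- out[order(out$station_id, out$index_name, out$date), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Warning days: dates whose daily maximum strictly exceeds a threshold
#'
#' Exceedance is strict (`>`) everywhere in the package, matching the
#' official rule ("exceeds" the 90 F cutoff).
#'
#' @param daily Data frame from [daily_maximum()] (columns `date`,
#'   `value`), for one station and one index.
#' @param threshold Threshold in the same unit as the series.
#' @return Sorted vector of `Date`s.
#' @export
warning_days <- function(daily, threshold) {
  stopifnot(length(threshold) == 1, is.finite(threshold))
  sort(daily$date[!is.na(daily$value) & daily$value > threshold])
}

#' Warning periods: maximal runs of consecutive warning days
#'
#' Groups a set of warning days into maximal runs of consecutive calendar
#' days and keeps runs of at least `min_len` days (the official level-3
#' rule uses 3; the level-4 rule uses 5).  Each retained run is labelled
#' with its duration category: `"3"`, `"4"`, or `"5+"` for five or more
#' days.
#'
#' @param days Vector of `Date`s (the warning days; order and duplicates
#'   are handled).
#' @param min_len Minimum run length in days, >= 1 (default 3).
#' @return Data frame `start`, `end`, `length`, `category`, one row per
#'   period, in chronological order.
#' @export
#' @examples
#' d <- as.Date("2017-06-01") + c(0:3, 9:15)
#' warning_periods(d)
warning_periods <- function(days, min_len = 3L) {
  stopifnot(min_len >= 1)
  days <- sort(unique(as.Date(days)))
  empty <- data.frame(start = as.Date(character()),
                      end = as.Date(character()),
                      length = integer(), category = character(),
                      stringsAsFactors = FALSE)
  if (length(days) == 0) return(empty)
  run_id <- cumsum(c(1L, as.integer(diff(days) != 1)))
  start <- as.Date(tapply(as.character(days), run_id, min))
  end <- as.Date(tapply(as.character(days), run_id, max))
  len <- as.integer(end - start + 1)
  keep <- len >= min_len
  out <- data.frame(
    start = start[keep], end = end[keep], length = len[keep],
    category = period_category(len[keep]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Duration category of a warning period
#'
#' @param length Period length(s) in days.
#' @return Character vector: `"3"`, `"4"`, or `"5+"`; `NA` below 3 days.
#' @export
period_category <- function(length) {
  ifelse(length >= 5, "5+",
         ifelse(length == 4, "4", ifelse(length == 3, "3", NA_character_)))
}
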