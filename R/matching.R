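# Agreement between the official heat-index warning system and an
# alternative-index system: single-day match percentage, per-duration-
# category hit rates, quality-of-hit statistics, and the one-variable-
# at-a-time response-surface sensitivity analysis.

#' Single-day match percentage
#'
#' Percentage of official warning days that are also flagged by the
#' alternative system: 100 |official intersect alt| / |official|.
#'
#' @param official_days,alt_days Vectors of `Date`s.
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' off <- as.Date("2017-07-01") + 0:9
#' alt <- c(off[1:2], as.Date("2017-08-01") + 0:7)
#' single_day_match(off, alt)  # 20
single_day_match <- function(official_days, alt_days) {
  official_days <- unique(as.Date(official_days))
  alt_days <- unique(as.Date(alt_days))
  if (length(official_days) == 0) {
    stop("single-day match is undefined without official warning days",
         call. = FALSE)
  }
  100 * sum(official_days %in% alt_days) / length(official_days)
}

#' Overlapping period pairs
#'
#' All (official, alternative) warning-period pairs that share at least
#' one calendar day, with the exact shared-day count.
#'
#' @param official,alt Period data frames from [warning_periods()]
#'   (columns `start`, `end`, `length`, `category`), same station.
#' @return Data frame with one row per overlapping pair: `official_idx`,
#'   `alt_idx` (row numbers into the inputs), `official_category`,
#'   `official_length`, `overlap_days`, `quality` (100 * overlap /
#'   official length).
#' @export
overlap_pairs <- function(official, alt) {
  empty <- data.frame(official_idx = integer(), alt_idx = integer(),
                      official_category = character(),
                      official_length = integer(),
                      overlap_days = integer(), quality = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(official) == 0 || nrow(alt) == 0) return(empty)
  grid <- expand.grid(official_idx = seq_len(nrow(official)),
                      alt_idx = seq_len(nrow(alt)))
  o <- official[grid$official_idx, ]
  a <- alt[grid$alt_idx, ]
  ov <- as.integer(pmin(o$end, a$end) - pmax(o$start, a$start) + 1)
  keep <- ov >= 1
  out <- data.frame(
    official_idx = grid$official_idx[keep],
    alt_idx = grid$alt_idx[keep],
    official_category = o$category[keep],
    official_length = o$length[keep],
    overlap_days = ov[keep],
    quality = 100 * ov[keep] / o$length[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$official_idx, out$alt_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hit rate per duration category
#'
#' Number of alternative warning periods that overlap official periods of
#' the category, relative to the number of official periods in that
#' category, as a percentage.  Can exceed 100 when several alternative
#' periods overlap one official period.  The complementary convention --
#' counting official periods captured (each at most once) -- is returned
#' as well, since the two differ exactly when multiple alternative periods
#' hit the same official event.
#'
#' @param pairs Data frame from [overlap_pairs()].
#' @param official Official-period data frame ([warning_periods()]).
#' @param category `"3"`, `"4"`, or `"5+"`.
#' @return List: `n_official`, `n_alt_overlapping`, `n_official_captured`,
#'   `hit_rate` (the alternative-period convention, %), and
#'   `hit_rate_captured` (official-captured convention, %).  When the
#'   category has no official period, `hit_rate` values are `NA` and
#'   `no_official_events` is TRUE (the asterisk case).
#' @export
hit_rate <- function(pairs, official, category) {
  n_off <- sum(official$category == category)
  if (n_off == 0) {
    return(list(n_official = 0L, n_alt_overlapping = NA_integer_,
                n_official_captured = NA_integer_, hit_rate = NA_real_,
                hit_rate_captured = NA_real_, no_official_events = TRUE))
  }
  p <- pairs[pairs$official_category == category, , drop = FALSE]
  n_alt <- length(unique(p$alt_idx))
  n_cap <- length(unique(p$official_idx))
  list(n_official = as.integer(n_off),
       n_alt_overlapping = as.integer(n_alt),
       n_official_captured = as.integer(n_cap),
       hit_rate = 100 * n_alt / n_off,
       hit_rate_captured = 100 * n_cap / n_off,
       no_official_events = FALSE)
}

#' Mean quality of hit(s) per duration category
#'
#' For every overlapping pair in the category, the quality is
#' 100 * overlap days / official period length; the category value is the
#' mean over pairs.  Every pair overlaps by construction (>= 1 day), so
#' all contributing values are positive; when the category has no pair the
#' quality is reported as missing, not as zero.
#'
#' @param pairs Data frame from [overlap_pairs()].
#' @param category `"3"`, `"4"`, or `"5+"`.
#' @return Mean quality in (0, 100\], or `NA_real_` when no pair exists.
#' @export
quality_of_hits <- function(pairs, category) {
  q <- pairs$quality[pairs$official_category == category]
  q <- q[!is.na(q) & q > 0]  # guard; pairs always overlap >= 1 day
  if (length(q) == 0) return(NA_real_)
  mean(q)
}

#' Full match report for one station and index pair
#'
#' Orchestrates the agreement metrics: single-day match percentage,
#' per-category (3 / 4 / 5+) hit rates and mean qualities, total
#' warning-day counts of both systems, and the number of false alarms
#' (alternative periods overlapping no official period).
#'
#' @param official_daily Daily-maximum heat-index series (one station),
#'   values in degrees Fahrenheit.
#' @param alt_daily Daily-maximum series of the alternative index (same
#'   station), degrees Celsius.
#' @param alt_threshold Warning threshold for the alternative index.
#' @param cutoff_f Official cutoff, degrees Fahrenheit (default 90).
#' @param min_len Minimum period length (default 3).
#' @param station_id,index_name,threshold_mode Labels copied into the
#'   report.
#' @return A list of class `"match_report"`: see fields in the
#'   description.
#' @export
build_match_report <- function(official_daily, alt_daily, alt_threshold,
                               cutoff_f = 90, min_len = 3L,
                               station_id = NA_character_,
                               index_name = NA_character_,
                               threshold_mode = NA_character_) {
  common <- as.Date(intersect(official_daily$date, alt_daily$date),
                    origin = "1970-01-01")
  official_daily <- official_daily[official_daily$date %in% common, ,
                                   drop = FALSE]
  alt_daily <- alt_daily[alt_daily$date %in% common, , drop = FALSE]

  off_days <- official_warning_days(official_daily, cutoff_f)
  alt_days <- warning_days(alt_daily, alt_threshold)
  off_periods <- warning_periods(off_days, min_len)
  alt_periods <- warning_periods(alt_days, min_len)
  pairs <- overlap_pairs(off_periods, alt_periods)

  cats <- c("3", "4", "5+")
  per_cat <- lapply(cats, function(cc) {
    hr <- hit_rate(pairs, off_periods, cc)
    hr$mean_quality <- quality_of_hits(pairs, cc)
    hr
  })
  names(per_cat) <- cats

  false_alarms <- if (nrow(alt_periods) == 0) 0L else {
    sum(!seq_len(nrow(alt_periods)) %in% pairs$alt_idx)
  }

  structure(list(
    station_id = station_id,
    index_name = index_name,
    threshold_mode = threshold_mode,
    single_day_match = if (length(off_days)) {
      single_day_match(off_days, alt_days)
    } else NA_real_,
    categories = per_cat,
    n_official_days = length(off_days),
    n_alt_days = length(alt_days),
    n_official_periods = nrow(off_periods),
    n_alt_periods = nrow(alt_periods),
    false_alarms = as.integer(false_alarms)
  ), class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("Match report: station %s, index %s (%s thresholds)\n",
              x$station_id, x$index_name, x$threshold_mode))
  cat(sprintf("  warning days: official %d, alternative %d\n",
              x$n_official_days, x$n_alt_days))
  cat(sprintf("  single-day match: %s%%\n",
              formatC(x$single_day_match, digits = 1, format = "f")))
  for (cc in names(x$categories)) {
    ci <- x$categories[[cc]]
    if (isTRUE(ci$no_official_events)) {
      cat(sprintf("  %s-day events: no official periods (*)\n", cc))
    } else {
      cat(sprintf(
        "  %s-day events: %d official, hit rate %s%%, mean quality %s%%\n",
        cc, ci$n_official, formatC(ci$hit_rate, digits = 0, format = "f"),
        if (is.na(ci$mean_quality)) "-" else
          formatC(ci$mean_quality, digits = 0, format = "f")))
    }
  }
  cat(sprintf("  false alarms: %d alternative period(s)\n",
              x$false_alarms))
  invisible(x)
}

#' Flatten match reports to a data frame
#'
#' @param reports A list of `"match_report"` objects.
#' @return One row per report with per-category columns expanded.
#' @export
match_report_table <- function(reports) {
  if (inherits(reports, "match_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    row <- data.frame(
      station_id = r$station_id, index_name = r$index_name,
      threshold_mode = r$threshold_mode,
      single_day_match = r$single_day_match,
      n_official_days = r$n_official_days, n_alt_days = r$n_alt_days,
      false_alarms = r$false_alarms, stringsAsFactors = FALSE)
    for (cc in names(r$categories)) {
      ci <- r$categories[[cc]]
      suffix <- sub("\\+", "plus", cc)
      row[[paste0("n_official_", suffix)]] <- ci$n_official
      row[[paste0("hit_rate_", suffix)]] <- ci$hit_rate
      row[[paste0("quality_", suffix)]] <- ci$mean_quality
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------

#' One-variable-at-a-time response surface of an index
#'
#' Evaluates an index along a grid of one input variable while all other
#' inputs stay frozen at a base point, and summarizes the sensitivity as
#' the least-squares slope of index value against the varied input.  Asking
#' for a variable the index does not use is an error (the curve would be
#' flat by construction, not by physics).
#'
#' @param index_name One of the names in [index_catalog()].
#' @param base Named list with the base point: `ta` (degrees C), `rh` (%),
#'   `ws` (m/s), `rad` (W/m2), `zenith_deg` (degrees; only wbgt.sun).
#' @param varied One of `"ta"`, `"rh"`, `"ws"`, `"rad"`.
#' @param grid Numeric vector of values for the varied input.
#' @return Data frame `input`, `value` with attributes `slope` (per unit
#'   of the varied input) and `varied`.
#' @export
#' @examples
#' response_surface("swbgt", list(ta = 30, rh = 50, ws = 1, rad = 0),
#'                  "rh", seq(20, 100, by = 5))
response_surface <- function(index_name, base, varied, grid) {
  cat_tab <- index_catalog()
  row <- cat_tab[cat_tab$index_name == index_name, , drop = FALSE]
  if (nrow(row) == 0) {
    stop("unknown index: ", index_name, call. = FALSE)
  }
  uses <- c(ta = TRUE, rh = row$needs_rh, ws = row$needs_ws,
            rad = row$needs_rad)
  if (!varied %in% names(uses)) {
    stop("varied input must be one of ", paste(names(uses), collapse = ", "),
         call. = FALSE)
  }
  if (!uses[[varied]]) {
    stop("index ", index_name, " does not use input '", varied,
         "'; a response surface over it would be constant", call. = FALSE)
  }
  pt <- list(ta = base$ta, rh = base$rh, ws = base$ws, rad = base$rad,
             zenith_deg = base$zenith_deg)
  vals <- vapply(grid, function(g) {
    pt[[varied]] <- g
    .eval_index(index_name, pt)
  }, numeric(1))
  slope <- unname(stats::coef(stats::lm(vals ~ grid))[2])
  structure(data.frame(input = grid, value = vals),
            slope = slope, varied = varied, index_name = index_name)
}

# evaluate one index at a scalar meteorological point
.eval_index <- function(index_name, pt) {
  ta <- pt$ta; rh <- pt$rh; ws <- pt$ws
  switch(index_name,
    hi = heat_index(ta, rh),
    wbt = as.numeric(wet_bulb_temperature(ta, rh, warn = FALSE)),
    wbgt.shade = wbgt_shade(ta, dew_point(ta, rh)),
    wbgt.sun = wbgt_sun(ta, dew_point(ta, rh), ws, pt$rad,
                        if (is.null(pt$zenith_deg)) 30 else pt$zenith_deg),
    swbgt = simplified_wbgt(ta, rh),
    apparentTemp = apparent_temperature(ta, rh, ws),
    effectiveTemp = effective_temperature(ta, rh, ws),
    humidex = humidex(ta, rh),
    discomInd = discomfort_index(ta, rh)
  )
}
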