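# File I/O, run configuration and the end-to-end pipeline driver.
# Hourly station files are plain CSV with the dialect
# station_id,timestamp,ta_c,rh_pct,ws_ms,rad_wm2 (ISO 8601 timestamps,
# UTC); station metadata is station_id,name,lat,lon,elev_m.  All tabular
# outputs are written as CSV with a machine-readable JSON twin.

.STATION_COLS <- c("station_id", "timestamp", "ta_c", "rh_pct", "ws_ms",
                   "rad_wm2")

#' Read an hourly station CSV
#'
#' Validates the header, parses ISO 8601 timestamps as UTC, and checks the
#' physical ranges (rh in \[0, 100\], ws >= 0, rad >= 0); offending rows are
#' reported with their line numbers.
#'
#' @param path Path to the CSV file.
#' @return Station series data frame (see [generate_station()]).
#' @export
read_station_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.STATION_COLS, names(df))
  if (length(missing_cols)) {
    stop("station file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (anyNA(ts) && !anyNA(df$timestamp)) {
    bad <- which(is.na(ts))
    stop("unparseable timestamp(s) in ", path, " at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df$timestamp <- ts
  checks <- list(
    rh_pct = !is.na(df$rh_pct) & (df$rh_pct < 0 | df$rh_pct > 100),
    ws_ms = !is.na(df$ws_ms) & df$ws_ms < 0,
    rad_wm2 = !is.na(df$rad_wm2) & df$rad_wm2 < 0
  )
  for (col in names(checks)) {
    bad <- which(checks[[col]])
    if (length(bad)) {
      stop("out-of-range ", col, " in ", path, " at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           " (value ", df[[col]][bad[1]], ")", call. = FALSE)
    }
  }
  df[, intersect(c(.STATION_COLS, "episode"), names(df)), drop = FALSE]
}

#' Write an hourly station CSV
#'
#' @param series Station series data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_station_csv <- function(series, path) {
  out <- series[, .STATION_COLS, drop = FALSE]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read station metadata CSV
#'
#' @param path CSV with header `station_id,name,lat,lon,elev_m`.
#' @return Data frame of station metadata.
#' @export
read_station_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "name", "lat", "lon", "elev_m")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("metadata file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a table as CSV plus JSON twin
#'
#' @param df Data frame.
#' @param path_csv Output CSV path; the JSON twin replaces the extension
#'   with `.json`.
#' @return `path_csv`, invisibly.
#' @export
write_table_pair <- function(df, path_csv) {
  utils::write.csv(df, path_csv, row.names = FALSE)
  path_json <- sub("\\.csv$", ".json", path_csv)
  if (identical(path_json, path_csv)) path_json <- paste0(path_csv, ".json")
  jsonlite::write_json(df, path_json, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", POSIXt = "ISO8601")
  invisible(path_csv)
}

#' Run configuration for the comparison pipeline
#'
#' Collects every tunable decision of the analysis: the official index and
#' its cutoffs, minimum warning-period durations, pooling window,
#' threshold mode, index list, local-time offset and daily completeness
#' rule, and the seed.
#'
#' @param indices Alternative indices to analyze.
#' @param official_index Name of the official index (default `"hi"`).
#' @param cutoff_level3_f,cutoff_level4_f Official cutoffs, degrees F.
#' @param min_len_level3,min_len_level4 Minimum consecutive warning days.
#' @param window_f Pooling window, degrees F; must bracket the level-3
#'   cutoff.
#' @param threshold_mode `"site_specific"` or `"region_wide"`.
#' @param tz_offset_hours Local standard time offset from UTC, hours.
#' @param min_hours_per_day Daily completeness rule (of 24 hours).
#' @param discomfort_variant Passed to [discomfort_index()].
#' @param sd_type Spatial-sd convention, `"population"` or `"sample"`.
#' @param seed Integer seed for any simulation stage.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(indices = setdiff(index_catalog()$index_name, "hi"),
                       official_index = "hi", cutoff_level3_f = 90,
                       cutoff_level4_f = 93, min_len_level3 = 3L,
                       min_len_level4 = 5L, window_f = c(88, 92),
                       threshold_mode = c("site_specific", "region_wide"),
                       tz_offset_hours = 1, min_hours_per_day = 18L,
                       discomfort_variant = "wet_bulb",
                       sd_type = "population", seed = 1L) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(window_f[1] < cutoff_level3_f, cutoff_level3_f < window_f[2],
            min_len_level3 >= 1, min_len_level4 >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full warning-comparison pipeline
#'
#' Chains the stages: hourly indices for every station, daily maxima,
#' threshold calibration (site-specific and region-wide), warning days and
#' periods for the official and each alternative system, and one match
#' report per station and index under the configured threshold mode.
#' Deterministic given the configuration and data.
#'
#' @param config A [run_config()].
#' @param series_list Named list of hourly station series.
#' @param meta Station metadata data frame (`station_id`, `lat`, `lon`,
#'   ...); required when `"wbgt.sun"` is among the indices.
#' @param outdir Optional directory; when given, threshold tables, warning
#'   days/periods and the match-report table are written there as
#'   CSV + JSON pairs.
#' @return List with `daily` (long daily maxima), `thresholds` (table from
#'   [calibrate_thresholds()]), `reports` (list of match reports) and
#'   `report_table`.
#' @export
run_pipeline <- function(config, series_list, meta = NULL, outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  all_ix <- unique(c(config$official_index, config$indices))
  daily_parts <- lapply(names(series_list), function(st) {
    ser <- series_list[[st]]
    lat <- lon <- NULL
    if (!is.null(meta)) {
      mrow <- meta[meta$station_id == st, , drop = FALSE]
      if (nrow(mrow)) { lat <- mrow$lat[1]; lon <- mrow$lon[1] }
    }
    if ("wbgt.sun" %in% all_ix && (is.null(lat) || is.null(lon))) {
      stop("wbgt.sun requested but no metadata (lat/lon) for station ",
           st, call. = FALSE)
    }
    hourly <- compute_indices(ser, indices = all_ix, lat = lat, lon = lon,
                              discomfort_variant = config$discomfort_variant)
    daily_maximum(hourly, tz_offset_hours = config$tz_offset_hours,
                  min_hours = config$min_hours_per_day)
  })
  daily <- do.call(rbind, daily_parts)

  thresholds <- calibrate_thresholds(
    daily, indices = setdiff(all_ix, config$official_index),
    cutoff_f = config$cutoff_level3_f, window = config$window_f,
    sd_type = config$sd_type)

  stations <- sort(unique(daily$station_id))
  hi_daily <- daily[daily$index_name == config$official_index, ,
                    drop = FALSE]
  reports <- list()
  for (st in stations) {
    for (ix in setdiff(all_ix, config$official_index)) {
      thr <- if (config$threshold_mode == "site_specific") {
        thresholds$threshold[thresholds$index_name == ix &
                               thresholds$mode == "site_specific" &
                               thresholds$station_id == st]
      } else {
        thresholds$threshold[thresholds$index_name == ix &
                               thresholds$mode == "region_wide"]
      }
      rep_i <- build_match_report(
        hi_daily[hi_daily$station_id == st, , drop = FALSE],
        daily[daily$index_name == ix & daily$station_id == st, ,
              drop = FALSE],
        alt_threshold = thr, cutoff_f = config$cutoff_level3_f,
        min_len = config$min_len_level3, station_id = st,
        index_name = ix, threshold_mode = config$threshold_mode)
      reports[[paste(st, ix, sep = ".")]] <- rep_i
    }
  }
  report_table <- match_report_table(reports)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_table_pair(thresholds, file.path(outdir, "thresholds.csv"))
    write_table_pair(report_table, file.path(outdir, "match_reports.csv"))
    write_table_pair(daily, file.path(outdir, "daily_maxima.csv"))
  }
  list(daily = daily, thresholds = thresholds, reports = reports,
       report_table = report_table)
}
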