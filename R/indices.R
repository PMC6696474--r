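# Direct thermal indices.  All inputs are hourly meteorological variables:
# ta (2 m air temperature, degrees C), rh (relative humidity, %), ws (10 m
# wind speed, m/s), rad (downwelling shortwave radiation, W/m2).  Every
# index is returned in degrees Celsius except the heat index, which is the
# official warning variable and is carried in degrees Fahrenheit with its
# defining lower bound at 80 F (values below are stored as exactly 0).

#' Heat index (NWS regression, degrees Fahrenheit)
#'
#' The official Swiss/US warning variable.  Follows the National Weather
#' Service algorithm: a simple Steadman-type formula is computed first and
#' averaged with the temperature; when that average reaches 80 F the full
#' Rothfusz multiple-regression equation is applied, together with the
#' low-humidity and high-humidity adjustment terms in their stated validity
#' ranges.  By definition the index is set to exactly 0 below 80 F, so the
#' stored series has no values in (0, 80).
#'
#' @param ta Air temperature, degrees Celsius.
#' @param rh Relative humidity, percent, in \[0, 100\].
#' @return Heat index in degrees Fahrenheit: either 0 or a value >= 80.
#' @export
#' @examples
#' heat_index(25, 50)  # below the 80 F bound -> 0
#' heat_index(35, 60)
heat_index <- function(ta, rh) {
  stopifnot(all(rh >= 0 & rh <= 100, na.rm = TRUE))
  n <- max(length(ta), length(rh))
  t_f <- rep_len(celsius_to_fahrenheit(ta), n)
  rh <- rep_len(rh, n)

  simple <- 0.5 * (t_f + 61 + (t_f - 68) * 1.2 + rh * 0.094)
  hi <- (simple + t_f) / 2

  use_reg <- !is.na(hi) & hi >= 80
  if (any(use_reg)) {
    t <- t_f[use_reg]
    r <- rh[use_reg]
    reg <- -42.379 + 2.04901523 * t + 10.14333127 * r -
      0.22475541 * t * r - 6.83783e-3 * t^2 - 5.481717e-2 * r^2 +
      1.22874e-3 * t^2 * r + 8.5282e-4 * t * r^2 - 1.99e-6 * t^2 * r^2
    adj_dry <- r < 13 & t >= 80 & t <= 112
    reg[adj_dry] <- reg[adj_dry] -
      (13 - r[adj_dry]) / 4 * sqrt((17 - abs(t[adj_dry] - 95)) / 17)
    adj_wet <- r > 85 & t >= 80 & t <= 87
    reg[adj_wet] <- reg[adj_wet] +
      (r[adj_wet] - 85) / 10 * (87 - t[adj_wet]) / 2
    hi[use_reg] <- reg
  }
  hi[!is.na(hi) & hi < 80] <- 0
  hi
}

#' Wet-bulb temperature (Stull empirical formula)
#'
#' Closed-form fit of the wet-bulb temperature to air temperature and
#' relative humidity, valid near sea-level pressure for roughly
#' rh in \[5, 99\] % and ta in \[-20, 50\] C with a stated accuracy of about
#' 1 C (so at saturation the result matches the dry-bulb temperature only
#' to within that envelope).  Outside the validity envelope the value is
#' still returned but flagged: a warning is raised and the result carries a
#' logical attribute `"out_of_range"`.  Warm-season warning screening only
#' exercises the well-behaved regime.
#'
#' @param ta Air temperature, degrees Celsius.
#' @param rh Relative humidity, percent.
#' @param warn Emit a warning when inputs fall outside the validity
#'   envelope (default TRUE).
#' @return Wet-bulb temperature in degrees Celsius, with attribute
#'   `out_of_range` when any input was outside the envelope.
#' @export
#' @examples
#' wet_bulb_temperature(30, 100)  # close to 30
#' wet_bulb_temperature(30, 40)
wet_bulb_temperature <- function(ta, rh, warn = TRUE) {
  n <- max(length(ta), length(rh))
  ta <- rep_len(ta, n)
  rh <- rep_len(rh, n)
  tw <- ta * atan(0.151977 * sqrt(rh + 8.313659)) +
    atan(ta + rh) - atan(rh - 1.676331) +
    0.00391838 * rh^1.5 * atan(0.023101 * rh) - 4.686035
  out <- !is.na(ta) & !is.na(rh) &
    (rh < 5 | rh > 99 | ta < -20 | ta > 50)
  if (any(out)) {
    if (warn) {
      warning(sprintf(
        "%d input(s) outside the empirical wet-bulb validity envelope; values returned but flagged",
        sum(out)
      ), call. = FALSE)
    }
    attr(tw, "out_of_range") <- out
  }
  tw
}

#' Wet bulb globe temperature in the shade
#'
#' Indoor/shade WBGT approximation: no strong radiation source and a fixed
#' wind speed of 1 m/s are assumed, so the globe temperature collapses to
#' the air temperature and the natural wet bulb to the psychrometric wet
#' bulb (the Bernard wind correction factor is 0.96 + 0.069 log10(ws),
#' which at 1 m/s fixes the natural wet bulb at
#' ta - 0.96 (ta - Tpwb)).  The index is the standard convex combination
#' 0.7 Tnwb + 0.3 ta.
#'
#' @param ta Air temperature, degrees Celsius.
#' @param td Dew-point temperature, degrees Celsius (td <= ta).
#' @param tol,max_iter Passed to [psychrometric_wet_bulb()].
#' @return Shade WBGT in degrees Celsius; equals ta for saturated air and
#'   is below ta otherwise.
#' @export
wbgt_shade <- function(ta, td, tol = 1e-3, max_iter = 100L) {
  tpwb <- psychrometric_wet_bulb(ta, td, tol = tol, max_iter = max_iter)
  tnwb <- ta - 0.96 * (ta - tpwb)
  0.7 * tnwb + 0.3 * ta
}

#' Simplified wet bulb globe temperature
#'
#' Affine combination of air temperature and vapor pressure,
#' \eqn{0.567 t_a + 0.393 e + 3.94} with e in hPa; strictly increasing in
#' both temperature and humidity and defined without iteration, which is
#' why it is the usual screening stand-in for the full WBGT.
#'
#' @param ta Air temperature, degrees Celsius.
#' @param rh Relative humidity, percent.
#' @return Simplified WBGT in degrees Celsius.
#' @export
simplified_wbgt <- function(ta, rh) {
  0.567 * ta + 0.393 * vapor_pressure(ta, rh) + 3.94
}

#' Apparent temperature (shade, wind-aware Steadman form)
#'
#' \eqn{t_a + 0.33 e - 0.70 ws - 4.00} with vapor pressure e in hPa: the
#' shade apparent temperature, with humidity raising and wind lowering the
#' perceived temperature.
#'
#' @param ta Air temperature, degrees Celsius.
#' @param rh Relative humidity, percent.
#' @param ws Wind speed at 10 m, m/s, >= 0.
#' @return Apparent temperature in degrees Celsius.
#' @export
apparent_temperature <- function(ta, rh, ws) {
  stopifnot(all(ws >= 0, na.rm = TRUE))
  ta + 0.33 * vapor_pressure(ta, rh) - 0.70 * ws - 4.00
}

#' Effective temperature (wind-dependent form)
#'
#' The wind-dependent effective temperature
#' \deqn{ET = 37 - \frac{37 - t_a}{0.68 - 0.0014\,rh +
#'   (1.76 + 1.4 ws^{0.75})^{-1}} - 0.29\, t_a (1 - 0.01\, rh)}
#' which anchors at the skin temperature 37 C: when ta = 37 the first
#' fraction vanishes and only the humidity correction remains.
#'
#' @param ta Air temperature, degrees Celsius.
#' @param rh Relative humidity, percent.
#' @param ws Wind speed, m/s, >= 0.
#' @return Effective temperature in degrees Celsius.
#' @export
effective_temperature <- function(ta, rh, ws) {
  stopifnot(all(ws >= 0, na.rm = TRUE))
  37 - (37 - ta) / (0.68 - 0.0014 * rh + 1 / (1.76 + 1.4 * ws^0.75)) -
    0.29 * ta * (1 - 0.01 * rh)
}

#' Humidex
#'
#' Air temperature plus a vapor-pressure excess term,
#' \eqn{t_a + 0.5555 (e - 10)} with e the dew-point-derived vapor pressure
#' in hPa (the package-wide Magnus set).  Equals ta exactly when e = 10 hPa.
#' Undefined at rh = 0 because the dew point is.
#'
#' @param ta Air temperature, degrees Celsius.
#' @param rh Relative humidity, percent, in (0, 100\].
#' @return Humidex in degrees Celsius.
#' @export
humidex <- function(ta, rh) {
  td <- dew_point(ta, rh)  # errors on rh <= 0
  e <- saturation_vapor_pressure(td)
  ta + 0.5555 * (e - 10)
}

#' Discomfort index
#'
#' Default variant is the wet-bulb-based form
#' \eqn{0.5 T_w + 0.5 t_a} with the empirical wet-bulb temperature of
#' [wet_bulb_temperature()]; at saturation it therefore equals ta up to the
#' wet-bulb formula's tolerance.  The classical
#' temperature-humidity variant
#' \eqn{t_a - 0.55 (1 - 0.01 rh)(t_a - 14.5)} is available behind
#' `variant = "thom"`; both take only temperature and humidity as inputs.
#'
#' @param ta Air temperature, degrees Celsius.
#' @param rh Relative humidity, percent.
#' @param variant `"wet_bulb"` (default) or `"thom"`.
#' @return Discomfort index in degrees Celsius.
#' @export
discomfort_index <- function(ta, rh, variant = c("wet_bulb", "thom")) {
  variant <- match.arg(variant)
  if (variant == "wet_bulb") {
    tw <- wet_bulb_temperature(ta, rh, warn = FALSE)
    0.5 * as.numeric(tw) + 0.5 * ta
  } else {
    ta - 0.55 * (1 - 0.01 * rh) * (ta - 14.5)
  }
}

# ---------------------------------------------------------------------------

#' Names, units and required inputs of the supported indices
#'
#' @return A data frame with one row per index: `index_name`, `unit`, and
#'   logical columns for each required meteorological input (temperature is
#'   required by all).
#' @export
index_catalog <- function() {
  data.frame(
    index_name = c("hi", "wbt", "wbgt.shade", "wbgt.sun", "swbgt",
                   "apparentTemp", "effectiveTemp", "humidex", "discomInd"),
    unit = c("degF", rep("degC", 8)),
    needs_rh = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    needs_ws = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    needs_rad = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                  FALSE),
    stringsAsFactors = FALSE
  )
}

#' Compute heat-stress indices for an hourly station series
#'
#' Evaluates the requested indices at every hour of a station series and
#' returns them in long format.  The dew point is derived internally from
#' temperature and humidity; the sun WBGT additionally needs the station
#' latitude/longitude (for solar geometry) and the measured shortwave
#' radiation.
#'
#' @param series A station series data frame with columns `station_id`,
#'   `timestamp` (POSIXct, UTC), `ta_c`, `rh_pct`, `ws_ms`, `rad_wm2`
#'   (see [read_station_csv()] / [generate_station()]).
#' @param indices Character vector of index names from [index_catalog()];
#'   default all nine.
#' @param lat,lon Station coordinates in decimal degrees; required only
#'   when `"wbgt.sun"` is requested.
#' @param discomfort_variant Passed to [discomfort_index()].
#' @return Long data frame `station_id`, `timestamp`, `index_name`,
#'   `value`, `unit`.
#' @export
compute_indices <- function(series, indices = index_catalog()$index_name,
                            lat = NULL, lon = NULL,
                            discomfort_variant = "wet_bulb") {
  cat_tab <- index_catalog()
  unknown <- setdiff(indices, cat_tab$index_name)
  if (length(unknown)) {
    stop("unknown index name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ta <- series$ta_c
  rh <- series$rh_pct
  ws <- series$ws_ms
  rad <- series$rad_wm2
  # dew point needed by the WBGT family; guard rh = 0 rows with NA
  td <- rep(NA_real_, length(ta))
  ok <- !is.na(rh) & rh > 0 & !is.na(ta)
  td[ok] <- dew_point(ta[ok], rh[ok])

  vals <- lapply(indices, function(ix) {
    switch(ix,
      hi = heat_index(ta, rh),
      wbt = as.numeric(wet_bulb_temperature(ta, rh, warn = FALSE)),
      wbgt.shade = {
        v <- rep(NA_real_, length(ta))
        v[ok] <- wbgt_shade(ta[ok], td[ok])
        v
      },
      wbgt.sun = {
        if (is.null(lat) || is.null(lon)) {
          stop("wbgt.sun requires station latitude and longitude",
               call. = FALSE)
        }
        if (is.null(rad) || all(is.na(rad))) {
          stop("wbgt.sun requires the shortwave radiation column",
               call. = FALSE)
        }
        zen <- solar_zenith(series$timestamp, lat, lon)
        v <- rep(NA_real_, length(ta))
        v[ok] <- wbgt_sun(ta[ok], td[ok], ws[ok], rad[ok], zen[ok])
        v
      },
      swbgt = simplified_wbgt(ta, rh),
      apparentTemp = apparent_temperature(ta, rh, ws),
      effectiveTemp = effective_temperature(ta, rh, ws),
      humidex = {
        v <- rep(NA_real_, length(ta))
        v[ok] <- humidex(ta[ok], rh[ok])
        v
      },
      discomInd = discomfort_index(ta, rh, variant = discomfort_variant)
    )
  })
  out <- data.frame(
    station_id = rep(series$station_id, length(indices)),
    timestamp = rep(series$timestamp, length(indices)),
    index_name = rep(indices, each = nrow(series)),
    value = unlist(vals, use.names = FALSE),
    unit = rep(cat_tab$unit[match(indices, cat_tab$index_name)],
               each = nrow(series)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
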