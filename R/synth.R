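# Seeded synthetic hourly weather for a network of stations.  The
# generator reproduces the statistical structure the downstream analysis
# consumes -- seasonal and diurnal temperature cycles, AR(1) synoptic
# variability, humidity anticorrelated with the diurnal temperature
# anomaly (optionally bimodal), day/night shortwave radiation modulated by
# cloudiness tied to humidity, positive lognormal wind, and occasional
# multi-day heat episodes hot and long enough to trip the official
# heat-index warning rule -- so every stage of the pipeline is testable
# without station archives.

#' Climate specification for one synthetic station
#'
#' Defaults emulate a Swiss lowland (< 600 m) station: annual-mean 2 m
#' temperature around 10 C with a seasonal half-range of 9.5 C (July mean
#' near 19.5 C), a 5 C diurnal half-range peaking mid-afternoon, daily
#' AR(1) synoptic variability, relative humidity anticorrelated with the
#' diurnal temperature anomaly, moderate lognormal wind, and on average
#' 1.5 summer heat episodes per year of mean length 4 days boosting
#' temperature by 9 C, which yields a realistic handful of official
#' warning days per year.
#'
#' @param station_id Station identifier.
#' @param lat,lon,elev_m Coordinates (decimal degrees) and elevation (m).
#' @param t_mean Annual mean temperature, degrees C.
#' @param seasonal_amp Seasonal half-range of the daily-mean cycle, C.
#' @param diurnal_amp Diurnal half-range, C.
#' @param ar1_coef,ar1_sd Daily AR(1) coefficient in \[0, 1) and innovation
#'   standard deviation (C) of the synoptic component.
#' @param rh_base Base relative humidity, %.
#' @param rh_ta_coupling Humidity response to the diurnal temperature
#'   anomaly, % per degree C (applied with a negative sign).
#' @param rh_noise_sd Hourly humidity noise standard deviation, %.
#' @param rh_moist_weight Probability in \[0, 1\] that a day belongs to a
#'   moist humidity mode shifted `rh_moist_shift` % upwards: at weights
#'   around 0.4-0.6 the humidity distribution becomes bimodal, emulating
#'   stations with two humidity regimes.
#' @param rh_moist_shift Upward humidity shift of the moist mode, %.
#' @param ws_meanlog,ws_sdlog Lognormal wind-speed parameters (m/s scale).
#' @param episode_rate Mean number of heat episodes per summer
#'   (June-August).
#' @param episode_mean_duration Mean episode length, days (>= 1).
#' @param episode_boost Additive temperature boost during episodes, C.
#' @param episode_moist_prob Probability an episode is humid (humidity
#'   pinned high) rather than dry (pinned low).
#' @param seed Integer seed owning all randomness of this station.
#' @return A list of class `"climate_spec"`.
#' @export
climate_spec <- function(station_id = "SYN1", lat = 47.0, lon = 8.0,
                         elev_m = 450, t_mean = 10, seasonal_amp = 9.5,
                         diurnal_amp = 5, ar1_coef = 0.7, ar1_sd = 1.8,
                         rh_base = 72, rh_ta_coupling = 2.5,
                         rh_noise_sd = 7, rh_moist_weight = 0,
                         rh_moist_shift = 18, ws_meanlog = log(2.2),
                         ws_sdlog = 0.45, episode_rate = 1.5,
                         episode_mean_duration = 4, episode_boost = 9,
                         episode_moist_prob = 0.5, seed = 1L) {
  stopifnot(seasonal_amp >= 0, diurnal_amp >= 0,
            ar1_coef >= 0, ar1_coef < 1, ar1_sd >= 0,
            episode_rate >= 0, episode_mean_duration >= 1,
            rh_moist_weight >= 0, rh_moist_weight <= 1)
  structure(as.list(environment()), class = "climate_spec")
}

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

#' Generate an hourly station series
#'
#' Builds `years` years of hourly (ta, rh, ws, rad) from a
#' [climate_spec()].  Temperature is seasonal cycle + diurnal cycle +
#' daily AR(1) synoptic anomaly + additive episode boosts; humidity is the
#' base level minus the coupling times the diurnal temperature anomaly,
#' plus noise, day-level moist-mode shifts and episode pinning, clipped to
#' \[5, 100\] %; radiation follows a half-sine daylight arc scaled by season
#' and damped by humidity-linked cloudiness (exactly 0 at night hours);
#' wind is positive lognormal noise.  Fully reproducible from the spec's
#' seed, which owns every draw.
#'
#' @param spec A [climate_spec()].
#' @param years Number of calendar years, >= 1.
#' @param start_year First calendar year (default 2001).
#' @return Data frame `station_id`, `timestamp` (POSIXct UTC), `ta_c`,
#'   `rh_pct`, `ws_ms`, `rad_wm2`, plus an `"episode"` logical column
#'   marking boosted hours.
#' @export
generate_station <- function(spec, years, start_year = 2001) {
  stopifnot(inherits(spec, "climate_spec"), years >= 1)
  .with_seed(spec$seed, {
    t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", start_year), tz = "UTC")
    t1 <- as.POSIXct(sprintf("%d-01-01 00:00:00", start_year + years),
                     tz = "UTC")
    ts <- seq(t0, t1 - 3600, by = 3600)
    n <- length(ts)
    lt <- as.POSIXlt(ts, tz = "UTC")
    doy <- lt$yday + 1
    hour_local <- (lt$hour + 1) %% 24  # fixed UTC+1 local standard time
    day_index <- as.integer(as.Date(ts, tz = "UTC") -
                              as.Date(t0, tz = "UTC")) + 1L
    n_days <- max(day_index)

    seasonal <- spec$t_mean +
      spec$seasonal_amp * cos(2 * pi * (doy - 200) / 365.25)
    diurnal <- spec$diurnal_amp * cos(2 * pi * (hour_local - 14.5) / 24)

    # daily AR(1) synoptic anomaly, constant within a day
    innov <- stats::rnorm(n_days, 0, spec$ar1_sd)
    syn <- numeric(n_days)
    syn[1] <- innov[1] / sqrt(max(1 - spec$ar1_coef^2, 1e-12))
    for (d in 2:n_days) {
      syn[d] <- spec$ar1_coef * syn[d - 1] + innov[d]
    }
    synoptic <- syn[day_index]

    # summer heat episodes: additive block boosts with a moist/dry flag
    boost <- numeric(n_days)
    moist_flag <- rep(NA, n_days)  # NA = no episode
    dates <- as.Date(t0, tz = "UTC") + (seq_len(n_days) - 1)
    dlt <- as.POSIXlt(dates)
    for (yr in start_year:(start_year + years - 1)) {
      in_summer <- which(dlt$year + 1900 == yr & dlt$mon + 1 >= 6 &
                           dlt$mon + 1 <= 8)
      if (!length(in_summer) || spec$episode_rate <= 0) next
      n_ep <- stats::rpois(1, spec$episode_rate)
      if (n_ep == 0) next
      starts <- sample(in_summer, n_ep, replace = TRUE)
      durs <- 1 + stats::rpois(n_ep, max(spec$episode_mean_duration - 1, 0))
      moist <- stats::runif(n_ep) < spec$episode_moist_prob
      for (k in seq_len(n_ep)) {
        idx <- starts[k]:min(starts[k] + durs[k] - 1, n_days)
        boost[idx] <- pmax(boost[idx], spec$episode_boost)
        moist_flag[idx] <- moist[k]
      }
    }
    episode_hour <- boost[day_index] > 0
    ta <- seasonal + diurnal + synoptic + boost[day_index]

    # humidity: anticorrelated with the diurnal anomaly; moist-mode days;
    # episodes pin the level high (humid) or low (dry)
    moist_day <- stats::runif(n_days) < spec$rh_moist_weight
    rh_level <- rep(spec$rh_base, n) +
      ifelse(moist_day[day_index], spec$rh_moist_shift, 0)
    ep_moist <- moist_flag[day_index]
    rh_level[episode_hour & ep_moist %in% TRUE] <- spec$rh_base + 8
    rh_level[episode_hour & ep_moist %in% FALSE] <- spec$rh_base - 25
    rh <- rh_level - spec$rh_ta_coupling * diurnal -
      1.2 * synoptic + stats::rnorm(n, 0, spec$rh_noise_sd)
    rh <- pmin(pmax(rh, 5), 100)

    # shortwave: half-sine daylight arc, seasonal amplitude, cloud damping
    season_frac <- 0.5 + 0.5 * cos(2 * pi * (doy - 172) / 365.25)
    arc <- sin(pi * (hour_local - 6) / 12)
    arc[hour_local < 6 | hour_local > 18] <- 0
    arc <- pmax(arc, 0)
    clear <- (180 + 770 * season_frac) * arc
    cloud <- 1 - 0.7 * pmin(pmax((rh - 40) / 60, 0), 1)
    cloud <- cloud * exp(stats::rnorm(n, 0, 0.15))
    rad <- pmin(pmax(clear * cloud, 0), 1100)
    rad[arc == 0] <- 0

    ws <- stats::rlnorm(n, spec$ws_meanlog, spec$ws_sdlog)

    data.frame(
      station_id = spec$station_id, timestamp = ts,
      ta_c = ta, rh_pct = rh, ws_ms = ws, rad_wm2 = rad,
      episode = episode_hour, stringsAsFactors = FALSE
    )
  })
}

#' Generate a network of synthetic stations
#'
#' Each station draws from its own substream: station `i` runs with seed
#' `master_seed + 104729 * i` (kept inside the 32-bit integer range), so
#' the network is reproducible from one master seed and stations are
#' mutually independent.
#'
#' @param specs List of [climate_spec()]s with distinct `station_id`s.
#' @param years Number of years per station.
#' @param master_seed Integer master seed; overrides each spec's own seed.
#' @param start_year First calendar year.
#' @return Named list of station series (see [generate_station()]).
#' @export
generate_network <- function(specs, years, master_seed = 1L,
                             start_year = 2001) {
  ids <- vapply(specs, function(s) s$station_id, character(1))
  if (anyDuplicated(ids)) {
    stop("station ids must be distinct: ",
         paste(ids[duplicated(ids)], collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    sp$seed <- (as.numeric(master_seed) + 104729 * i) %% 2147483647
    generate_station(sp, years, start_year = start_year)
  })
  names(out) <- ids
  out
}

#' Calibrate a climate spec to a target warning-day rate
#'
#' Adjusts the episode temperature boost by bisection until the simulated
#' mean annual number of official warning days (daily-maximum heat index
#' strictly above `cutoff_f`) is within `tol_frac` of the target, on a
#' fixed calibration seed.  A target of 0 simply disables episodes.
#'
#' @param spec A [climate_spec()].
#' @param target_days_per_year Desired mean official warning days per
#'   year, >= 0.
#' @param years Simulation length used for each evaluation.
#' @param cutoff_f Official cutoff, degrees Fahrenheit.
#' @param tol_frac Relative tolerance around the target (default 0.2).
#' @param boost_range Search interval for the episode boost, degrees C.
#' @param max_iter Maximum bisection steps.
#' @return The calibrated `climate_spec` with attribute `achieved_rate`.
#' @export
calibrate_to_warning_rate <- function(spec, target_days_per_year,
                                      years = 10, cutoff_f = 90,
                                      tol_frac = 0.2,
                                      boost_range = c(0, 25),
                                      max_iter = 14L) {
  stopifnot(target_days_per_year >= 0)
  if (target_days_per_year == 0) {
    spec$episode_rate <- 0
    spec$episode_boost <- 0
    attr(spec, "achieved_rate") <- 0
    return(spec)
  }
  rate_for <- function(boost) {
    sp <- spec
    sp$episode_boost <- boost
    ser <- generate_station(sp, years)
    hi_hourly <- data.frame(station_id = ser$station_id,
                            timestamp = ser$timestamp,
                            index_name = "hi",
                            value = heat_index(ser$ta_c, ser$rh_pct),
                            stringsAsFactors = FALSE)
    daily <- daily_maximum(hi_hourly)
    length(official_warning_days(daily, cutoff_f)) / years
  }
  lo <- boost_range[1]; hi <- boost_range[2]
  r_lo <- rate_for(lo); r_hi <- rate_for(hi)
  if (target_days_per_year < r_lo || target_days_per_year > r_hi) {
    stop("target warning-day rate ", target_days_per_year,
         " is outside the achievable range [", signif(r_lo, 3), ", ",
         signif(r_hi, 3), "] for this spec", call. = FALSE)
  }
  achieved <- r_lo
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r_mid <- rate_for(mid)
    if (abs(r_mid - target_days_per_year) <=
        tol_frac * target_days_per_year) {
      spec$episode_boost <- mid
      attr(spec, "achieved_rate") <- r_mid
      return(spec)
    }
    if (r_mid < target_days_per_year) lo <- mid else hi <- mid
    achieved <- r_mid
  }
  stop("calibration did not reach the target rate within ", max_iter,
       " bisection steps (last achieved ", signif(achieved, 3), ")",
       call. = FALSE)
}
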