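# Outdoor WBGT by the Liljegren energy-balance model: the natural wet-bulb
# and black-globe temperatures are solved from coupled radiative,
# convective and (for the wick) evaporative fluxes, then combined as
# 0.7 Tnwb + 0.2 Tg + 0.1 Ta.  Both balances have strictly decreasing
# residuals in the unknown temperature, so each is solved by vectorized
# bisection on a physical bracket -- guaranteed convergence with no
# per-element root finder, which keeps multi-year hourly series tractable.

# physical constants (SI)
.STEFANB <- 5.6696e-8
.CP <- 1003.5            # J/(kg K) dry air
.M_AIR <- 28.97
.M_H2O <- 18.015
.R_GAS <- 8314.34
.R_AIR <- .R_GAS / .M_AIR
.PR <- .CP / (.CP + 1.25 * .R_AIR)   # Prandtl number
.RATIO <- .CP * .M_AIR / .M_H2O
.SOLAR_CONST <- 1367

# globe and wick geometry / radiative properties
.EMIS_GLOBE <- 0.95; .ALB_GLOBE <- 0.05; .DIAM_GLOBE <- 0.0508
.EMIS_WICK <- 0.95;  .ALB_WICK <- 0.4;   .DIAM_WICK <- 0.007
.LEN_WICK <- 0.0254
.EMIS_SFC <- 0.999;  .ALB_SFC <- 0.45

.viscosity <- function(tk) 1.458e-6 * tk^1.5 / (tk + 110.4)
.thermal_cond <- function(tk) (.CP + 1.25 * .R_AIR) * .viscosity(tk)
.h_evap <- function(tk) (313.15 - tk) / 30 * (-71100) + 2.4073e6
.esat_hpa <- function(tk) saturation_vapor_pressure(tk - 273.15)
.emis_atm <- function(e_hpa) 0.575 * e_hpa^0.143

.diffusivity <- function(tk, p_atm) {
  pcrit13 <- (36.4 * 218)^(1 / 3)
  tcrit512 <- (132 * 647.3)^(5 / 12)
  tcrit12 <- sqrt(132 * 647.3)
  mmix <- sqrt(1 / .M_AIR + 1 / .M_H2O)
  3.640e-4 * (tk / tcrit12)^2.334 * pcrit13 * tcrit512 * mmix / p_atm / 1e4
}

.h_sphere <- function(tk, p_hpa, speed) {
  density <- p_hpa * 100 / (.R_AIR * tk)
  re <- pmax(speed, 0.1) * density * .DIAM_GLOBE / .viscosity(tk)
  nu <- 2 + 0.6 * sqrt(re) * .PR^(1 / 3)
  nu * .thermal_cond(tk) / .DIAM_GLOBE
}

.h_cylinder <- function(tk, p_hpa, speed) {
  density <- p_hpa * 100 / (.R_AIR * tk)
  re <- pmax(speed, 0.1) * density * .DIAM_WICK / .viscosity(tk)
  nu <- 0.281 * re^0.6 * .PR^0.44
  nu * .thermal_cond(tk) / .DIAM_WICK
}

# direct-beam fraction of the measured global radiation, from the ratio of
# measured to top-of-atmosphere irradiance
.direct_fraction <- function(solar, cza) {
  toa <- .SOLAR_CONST * pmax(cza, 0)
  sstar <- ifelse(toa > 0, pmin(pmax(solar / toa, 1e-6), 0.85), 0)
  fdir <- ifelse(sstar > 0, exp(3 - 1.34 * sstar - 1.65 / sstar), 0)
  fdir[cza < 0.00873 | solar <= 0] <- 0
  pmin(pmax(fdir, 0), 0.9)
}

#' Black-globe temperature (energy balance)
#'
#' Iterative solution of the radiative/convective balance of a standard
#' 150 mm black globe: absorbed solar (direct + diffuse + surface-reflected)
#' and thermal radiation from sky and surface against convective exchange
#' with the air and the globe's own emission.  Damped fixed-point iteration
#' to an absolute tolerance.
#'
#' @param ta Air temperature, degrees Celsius.
#' @param td Dew point, degrees Celsius.
#' @param ws Wind speed, m/s.
#' @param rad Global shortwave radiation, W/m2.
#' @param zenith_deg Solar zenith angle, degrees.
#' @param pressure Surface pressure, hPa.
#' @param tol,max_iter Convergence tolerance (degrees C) and iteration cap.
#' @return Globe temperature, degrees Celsius.
#' @export
globe_temperature <- function(ta, td, ws, rad, zenith_deg,
                              pressure = 1013.25, tol = 1e-3,
                              max_iter = 100L) {
  n <- max(length(ta), length(td), length(ws), length(rad),
           length(zenith_deg))
  ta <- rep_len(ta, n); td <- rep_len(td, n); ws <- rep_len(ws, n)
  rad <- rep_len(rad, n); zen <- rep_len(zenith_deg, n)
  p <- rep_len(pressure, n)

  tair <- ta + 273.15
  cza <- pmax(cos(zen * pi / 180), 0)
  # Liljegren solar normalization: the measured global radiation cannot
  # exceed 85 % of the top-of-atmosphere irradiance; capping it keeps the
  # direct-beam term bounded at grazing sun angles
  solar <- pmin(rad, 0.85 * .SOLAR_CONST * cza)
  fdir <- .direct_fraction(solar, cza)
  ea <- .esat_hpa(td + 273.15)
  eatm <- .emis_atm(ea)
  tsfc <- tair
  # beam geometry term; cza floored where any direct beam exists
  czad <- pmax(cza, 0.00873)
  sterm <- solar / (2 * .EMIS_GLOBE * .STEFANB) * (1 - .ALB_GLOBE) *
    (fdir * (1 / (2 * czad) - 1) + 1 + .ALB_SFC)

  # residual of the balance is strictly decreasing in tg: bisect
  residual <- function(tg) {
    tref <- 0.5 * (tg + tair)
    h <- .h_sphere(tref, p, ws)
    rhs4 <- 0.5 * (eatm * tair^4 + .EMIS_SFC * tsfc^4) -
      h / (.EMIS_GLOBE * .STEFANB) * (tg - tair) + sterm
    pmax(rhs4, 0)^0.25 - tg
  }
  lo <- tair - 40
  hi <- tair + 150
  if (any(residual(lo) < 0 | residual(hi) > 0, na.rm = TRUE)) {
    stop("globe temperature bracket failed for some inputs", call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    if (all(hi - lo <= tol, na.rm = TRUE)) break
    mid <- 0.5 * (lo + hi)
    f <- residual(mid)
    pos <- !is.na(f) & f > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  0.5 * (lo + hi) - 273.15
}

#' Natural wet-bulb temperature (energy balance)
#'
#' Solution of the energy balance of a wetted wick exposed to wind and
#' radiation: evaporative cooling driven by the wick-air vapor pressure
#' difference, convective exchange, and net thermal plus solar radiative
#' gain.  The residual is strictly decreasing in the wick temperature, so
#' the root is found by vectorized bisection to an absolute tolerance.
#'
#' @inheritParams globe_temperature
#' @return Natural wet-bulb temperature, degrees Celsius.
#' @export
natural_wet_bulb <- function(ta, td, ws, rad, zenith_deg,
                             pressure = 1013.25, tol = 1e-3,
                             max_iter = 100L) {
  n <- max(length(ta), length(td), length(ws), length(rad),
           length(zenith_deg))
  ta <- rep_len(ta, n); td <- rep_len(td, n); ws <- rep_len(ws, n)
  rad <- rep_len(rad, n); zen <- rep_len(zenith_deg, n)
  p <- rep_len(pressure, n)

  tair <- ta + 273.15
  cza <- pmax(cos(zen * pi / 180), 0)
  # Liljegren solar normalization: the measured global radiation cannot
  # exceed 85 % of the top-of-atmosphere irradiance; capping it keeps the
  # direct-beam term bounded at grazing sun angles
  solar <- pmin(rad, 0.85 * .SOLAR_CONST * cza)
  fdir <- .direct_fraction(solar, cza)
  ea <- .esat_hpa(td + 273.15)
  eatm <- .emis_atm(ea)
  tsfc <- tair
  sza <- acos(pmin(pmax(cza, 0.00873), 1))  # capped for tan() at horizon
  density <- p * 100 / (.R_AIR * tair)
  sc <- .viscosity(tair) / (density * .diffusivity(tair, p / 1013.25))
  srad <- (1 - .ALB_WICK) * solar *
    ((1 - fdir) * (1 + 0.25 * .DIAM_WICK / .LEN_WICK) +
       fdir * (tan(sza) / pi + 0.25 * .DIAM_WICK / .LEN_WICK) + .ALB_SFC)

  # residual strictly decreasing in twb (evaporation and emission both
  # grow with wick temperature): bisect on a generous physical bracket
  residual <- function(twb) {
    tref <- 0.5 * (twb + tair)
    h <- .h_cylinder(tref, p, ws)
    fatm <- .STEFANB * .EMIS_WICK *
      (0.5 * (eatm * tair^4 + .EMIS_SFC * tsfc^4) - twb^4) + srad
    ewick <- .esat_hpa(twb)
    evap <- .h_evap(twb)
    tair - evap / .RATIO * (ewick - ea) / (p - ewick) *
      (.PR / sc)^0.56 + fatm / h - twb
  }
  lo <- pmin(td + 273.15, tair) - 15
  hi <- tair + 40
  if (any(residual(lo) < 0 | residual(hi) > 0, na.rm = TRUE)) {
    stop("natural wet-bulb bracket failed for some inputs", call. = FALSE)
  }
  for (i in seq_len(max_iter)) {
    if (all(hi - lo <= tol, na.rm = TRUE)) break
    mid <- 0.5 * (lo + hi)
    f <- residual(mid)
    pos <- !is.na(f) & f > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  0.5 * (lo + hi) - 273.15
}

#' Wet bulb globe temperature in the sun
#'
#' Outdoor WBGT = 0.7 Tnwb + 0.2 Tg + 0.1 ta, with the natural wet-bulb
#' and black-globe temperatures solved from the Liljegren-type energy
#' balances ([natural_wet_bulb()], [globe_temperature()]).  The measured
#' global shortwave radiation is used directly and split into direct and
#' diffuse components from the clearness ratio; solar geometry enters via
#' the zenith angle (see [solar_zenith()]).  With no radiation and 1 m/s
#' wind the result approaches the shade formulation [wbgt_shade()].
#'
#' @inheritParams globe_temperature
#' @return Outdoor WBGT, degrees Celsius.
#' @export
wbgt_sun <- function(ta, td, ws, rad, zenith_deg, pressure = 1013.25,
                     tol = 1e-3, max_iter = 100L) {
  stopifnot(all(rad >= 0, na.rm = TRUE), all(ws >= 0, na.rm = TRUE))
  tg <- globe_temperature(ta, td, ws, rad, zenith_deg, pressure, tol,
                          max_iter)
  tnwb <- natural_wet_bulb(ta, td, ws, rad, zenith_deg, pressure, tol,
                           max_iter)
  0.7 * tnwb + 0.2 * tg + 0.1 * ta
}
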