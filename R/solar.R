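# Solar position (zenith angle) from timestamp and station coordinates.
# Compact NOAA/Meeus solar-position algorithm: adequate to ~0.01 degree,
# far below what the globe-temperature energy balance can feel.

#' Solar zenith angle
#'
#' Computes the solar zenith angle for UTC timestamps at a given location
#' using the NOAA low-accuracy ephemeris (geometric mean longitude/anomaly,
#' equation of center, obliquity, equation of time, hour angle).  No
#' atmospheric refraction correction is applied; the energy-balance model
#' only consumes the cosine of the zenith.
#'
#' @param time POSIXct timestamps (interpreted in UTC).
#' @param lat Latitude in decimal degrees (north positive).
#' @param lon Longitude in decimal degrees (east positive).
#' @return Zenith angle in degrees; > 90 when the sun is below the horizon.
#' @export
#' @examples
#' solar_zenith(as.POSIXct("2003-08-10 12:00", tz = "UTC"), 47.5, 7.6)
solar_zenith <- function(time, lat, lon) {
  tt <- as.POSIXlt(time, tz = "UTC")
  # Julian day from Unix epoch (1970-01-01 00:00 UTC = JD 2440587.5)
  jd <- as.numeric(as.POSIXct(tt)) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525  # Julian century from J2000.0

  deg2rad <- pi / 180
  gmls <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eeo <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  ctr <- sin(gmas * deg2rad) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(2 * gmas * deg2rad) * (0.019993 - 0.000101 * jc) +
    sin(3 * gmas * deg2rad) * 0.000289
  stl <- gmls + ctr  # true longitude
  sal <- stl - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * jc) * deg2rad)
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc *
    (0.00059 - jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos((125.04 - 1934.136 * jc) * deg2rad)
  decl <- asin(sin(oc * deg2rad) * sin(sal * deg2rad))  # radians

  vary <- tan(oc / 2 * deg2rad)^2
  eqtime <- 4 / deg2rad * (vary * sin(2 * gmls * deg2rad) -
    2 * eeo * sin(gmas * deg2rad) +
    4 * eeo * vary * sin(gmas * deg2rad) * cos(2 * gmls * deg2rad) -
    0.5 * vary^2 * sin(4 * gmls * deg2rad) -
    1.25 * eeo^2 * sin(2 * gmas * deg2rad))  # minutes

  minutes_utc <- tt$hour * 60 + tt$min + tt$sec / 60
  tst <- (minutes_utc + eqtime + 4 * lon) %% 1440  # true solar time, min
  ha <- ifelse(tst / 4 < 0, tst / 4 + 180, tst / 4 - 180)  # degrees

  cos_zen <- sin(lat * deg2rad) * sin(decl) +
    cos(lat * deg2rad) * cos(decl) * cos(ha * deg2rad)
  acos(pmin(pmax(cos_zen, -1), 1)) / deg2rad
}
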