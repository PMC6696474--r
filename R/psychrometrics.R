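# Psychrometric helpers shared by all indices.  One Magnus constant set
# (over water) is used everywhere so that dew point, vapor pressure and the
# wet-bulb solvers are mutually consistent.

# Magnus constants over water; es in hPa, temperature in degrees Celsius.
.MAGNUS_A <- 17.27
.MAGNUS_B <- 237.7
.MAGNUS_E0 <- 6.105

#' Saturation vapor pressure over water
#'
#' Magnus-type formula \eqn{e_s(T) = 6.105 \exp(17.27 T / (237.7 + T))} with
#' temperature in degrees Celsius and the result in hPa.  The same constant
#' set backs every index in the package, so vapor pressure, dew point and
#' the wet-bulb solvers cannot drift apart.
#'
#' @param ta Air (or dew-point) temperature in degrees Celsius.
#' @return Saturation vapor pressure in hPa.
#' @export
#' @examples
#' saturation_vapor_pressure(25)
saturation_vapor_pressure <- function(ta) {
  .MAGNUS_E0 * exp(.MAGNUS_A * ta / (.MAGNUS_B + ta))
}

#' Actual vapor pressure from temperature and relative humidity
#'
#' @param ta Air temperature in degrees Celsius.
#' @param rh Relative humidity in percent, in \[0, 100\].
#' @return Vapor pressure in hPa; 0 at rh = 0, the saturation value at
#'   rh = 100, linear in rh in between.
#' @export
vapor_pressure <- function(ta, rh) {
  stopifnot(all(rh >= 0 & rh <= 100, na.rm = TRUE))
  rh / 100 * saturation_vapor_pressure(ta)
}

#' Dew-point temperature
#'
#' Inverts the Magnus relation: the dew point is the temperature at which
#' the actual vapor pressure would saturate.  Undefined at rh = 0.
#'
#' @param ta Air temperature in degrees Celsius.
#' @param rh Relative humidity in percent, must be > 0 (and <= 100 for a
#'   physically meaningful dew point <= ta).
#' @return Dew point in degrees Celsius; equals `ta` at rh = 100.
#' @export
#' @examples
#' dew_point(25, 100)  # 25
#' dew_point(30, 50)
dew_point <- function(ta, rh) {
  if (any(rh <= 0, na.rm = TRUE)) {
    stop("dew point is undefined for relative humidity <= 0 %", call. = FALSE)
  }
  stopifnot(all(rh <= 100, na.rm = TRUE))
  gamma <- log(rh / 100) + .MAGNUS_A * ta / (.MAGNUS_B + ta)
  .MAGNUS_B * gamma / (.MAGNUS_A - gamma)
}

#' Psychrometric wet-bulb temperature
#'
#' Solves the wet-bulb energy balance of Bernard and Pourmoghani (the
#' formulation behind the indoor/shade WBGT): find Tw between the dew point
#' and the dry-bulb temperature such that
#' \deqn{1556 e_d - 1.484 e_d T_w - 1556 e_s(T_w) + 1.484 e_s(T_w) T_w +
#'   1010 (T_a - T_w) = 0}
#' with vapor pressures in hPa.  The root is bracketed by `[td, ta]` and
#' found by vectorized bisection: 45 halvings bring the bracket below
#' 1e-3 degrees C for any physically sensible spread, with no per-element
#' `uniroot()` call, so multi-year hourly series stay cheap.
#'
#' @param ta Air temperature, degrees Celsius.
#' @param td Dew-point temperature, degrees Celsius; must satisfy td <= ta.
#' @param tol Absolute convergence tolerance in degrees Celsius.
#' @param max_iter Maximum number of bisection steps.
#' @return Wet-bulb temperature, degrees Celsius, with td <= Tw <= ta.
#' @export
psychrometric_wet_bulb <- function(ta, td, tol = 1e-3, max_iter = 100L) {
  n <- max(length(ta), length(td))
  ta <- rep_len(ta, n)
  td <- rep_len(td, n)
  if (any(td > ta + 1e-9, na.rm = TRUE)) {
    stop("dew point must not exceed air temperature", call. = FALSE)
  }
  td <- pmin(td, ta)
  # hPa saturation pressure, same Magnus set as everywhere else
  balance <- function(tw, ed) {
    ew <- saturation_vapor_pressure(tw)
    1556 * ed - 1.484 * ed * tw - 1556 * ew + 1.484 * ew * tw +
      1010 * (ta - tw)
  }
  ed <- saturation_vapor_pressure(td)
  lo <- td
  hi <- ta
  # balance(td) >= 0 and balance(ta) <= 0, so the bracket is valid; bisect.
  for (i in seq_len(max_iter)) {
    if (all(hi - lo <= tol, na.rm = TRUE)) break
    mid <- (lo + hi) / 2
    f <- balance(mid, ed)
    pos <- !is.na(f) & f > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  (lo + hi) / 2
}

#' Temperature unit conversions
#'
#' Exact affine conversions between degrees Fahrenheit and Celsius.  The
#' official warning rule is stated in degrees F while every alternative
#' index is carried in degrees C, so these show up throughout the
#' threshold machinery.
#'
#' @param x Temperature value(s).
#' @return Converted temperature.
#' @export
#' @examples
#' fahrenheit_to_celsius(90)  # 32.22...
#' celsius_to_fahrenheit(0)   # 32
fahrenheit_to_celsius <- function(x) (x - 32) * 5 / 9

#' @rdname fahrenheit_to_celsius
#' @export
celsius_to_fahrenheit <- function(x) x * 9 / 5 + 32
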