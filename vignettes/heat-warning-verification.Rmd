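---
title: "Comparing heat-warning systems: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing heat-warning systems: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatwarn)
```

# The problem

An official heat warning is a rule applied to a heat-stress index: in the
Swiss system, daily-maximum heat index (*hi*) strictly above 90 °F on at
least three consecutive days triggers a danger-level-3 warning (93 °F and
five days for level 4). Because *hi* is floored at 80 °F and carries no
ISO work-rest guidance, a warning service may want to know how a
*different* index — one with a continuous climatology, or a stronger
humidity response — would have reproduced the historical warning record.
`heatwarn` implements that retrospective comparison end to end: index
computation, threshold calibration, event detection and agreement
scoring, plus a synthetic data generator that makes every stage testable.

# Indices

All nine indices are *direct* thermal indices: functions of meteorological
variables only (2 m temperature, relative humidity, 10 m wind, global
shortwave radiation, and the dew point derived from temperature and
humidity). A single Magnus saturation formula
(e_s = 6.105·exp(17.27·T/(237.7 + T)) hPa, over water) backs every
psychrometric step — dew point, vapor pressure and both wet-bulb solvers —
so no two indices can disagree about the humidity they see.

| index | inputs | form |
|---|---|---|
| `hi` | T, RH | NWS algorithm: Steadman simple formula averaged with T gates the Rothfusz regression with its low-RH and high-RH adjustments; values below 80 °F are stored as exactly 0 |
| `wbt` | T, RH | Stull (2011) closed-form wet bulb; validity RH 5–99 %, T −20…50 °C, accuracy ≈ 1 °C |
| `wbgt.shade` | T, T_d | 0.7·T_nwb + 0.3·T with T_nwb = T − 0.96·(T − T_pwb), T_pwb from the Bernard psychrometric balance, wind fixed at 1 m/s |
| `wbgt.sun` | T, T_d, v, S, solar geometry | 0.7·T_nwb + 0.2·T_g + 0.1·T, Liljegren energy balances for wick and globe |
| `swbgt` | T, RH | 0.567·T + 0.393·e + 3.94 |
| `apparentTemp` | T, RH, v | T + 0.33·e − 0.70·v − 4.00 |
| `effectiveTemp` | T, RH, v | wind-dependent form anchored at 37 °C skin temperature |
| `humidex` | T, RH | T + 0.5555·(e − 10), e from the dew point |
| `discomInd` | T, RH | 0.5·T + 0.5·T_w (Stull); Thom's T − 0.55·(1 − 0.01·RH)·(T − 14.5) behind `variant = "thom"` |

The heat index is carried in °F (the unit of the official rule); all other
indices are in °C.

Two genuinely open formulation choices had to be fixed. The discomfort
index appears in the literature both as a wet-bulb average and as Thom's
temperature–humidity form; both consume only (T, RH). We default to the
wet-bulb average because it has the cleaner saturated limit
(DI → T as RH → 100) and expose the Thom form behind a flag. For the
shade WBGT we use the Bernard indoor formulation with the 0.96 wind
factor at the assumed 1 m/s; the natural wet bulb then interpolates
between the psychrometric wet bulb and the air temperature.

## Numerical choices

Three solvers are iterative. The psychrometric wet bulb solves the
Bernard balance
1556·e_d − 1.484·e_d·T_w − 1556·e_s(T_w) + 1.484·e_s(T_w)·T_w +
1010·(T − T_w) = 0 (pressures in hPa); the Liljegren wick and globe solve
radiative–convective(–evaporative) balances with the standard geometry
(150 mm globe, 7 mm × 25.4 mm wick), Nusselt-number convection
correlations, and the measured global radiation split into direct and
diffuse fractions from the clearness ratio. All three residuals are
strictly monotone in the unknown temperature, so each is solved by
*vectorized bisection* on a physical bracket — tolerance 10⁻³ °C, at most
100 halvings, no per-element root finder. Bisection was chosen over
damped fixed-point iteration because the fixed point oscillates for
strongly irradiated inputs while bisection cannot fail on a valid
bracket; whole hourly series are solved as single vectors, which keeps a
20-station decade (≈ 1.75 million hours) near a minute of compute.
Following the original energy-balance code, measured radiation is capped
at 85 % of the top-of-atmosphere irradiance, which bounds the
direct-beam term at grazing sun angles. Solar zenith angles come from the
compact NOAA ephemeris (adequate to ≈ 0.01°).

Stull's formula is used outside its stated envelope only with a warning
and an `out_of_range` flag: warm-season screening never leaves the
envelope, and hard errors would be hostile in year-round series.

At zero radiation and 1 m/s wind the sun and shade WBGT formulations
describe the same situation and agree within 0.5 °C for dew-point
depressions up to ≈ 8 °C (RH ≳ 60 %), the regime in which heat-index
warnings occur. In drier air the two published approximations genuinely
diverge, up to ≈ 0.7 °C at 14 °C depression — Bernard's fixed wind factor
and Liljegren's radiatively coupled wick are different idealizations —
and we document rather than suppress that gap.

# Threshold calibration

**Site-specific (frequency matching).** Count the station's official
warning days n (daily-max *hi* strictly above 90 °F), sort the station's
daily maxima of the alternative index ascending, and take the value
followed by exactly n larger values — the (N − n)-th order statistic. In
the tie-free case exactly n days then exceed the threshold, so the
alternative system reproduces the official warning-day count by
construction. Ties make an exact count impossible; we still return the
order statistic and report the achieved count as an attribute rather than
perturbing data. "Exceeds" is strict (`>`) everywhere in the package —
one convention, stated once.

**Region-wide (pooled-window averaging).** Pool all station-days, select
those with 88 °F < *hi* < 92 °F (both bounds strict and configurable;
the sources write strict inequalities) and average the alternative
index over them. This yields one threshold for the whole network, at the
price of no longer preserving per-station warning counts.

**Spatial summary.** The mean and standard deviation of site-specific
thresholds over stations; the population convention (divide by n) is the
default since the estimator is descriptive, with the sample convention a
flag away.

The two network-wide numbers — the pooled-window threshold and the mean
of site thresholds — agree closely but not perfectly, and the residual
is *systematic*, not sampling noise: days with *hi* just below 90 °F
outnumber days just above (tail densities decrease), and any index that
is not a deterministic function of *hi* regresses toward its conditional
mean inside the window, which sits below the frequency-matched order
statistic. On a homogeneous 20-station synthetic decade the gap is
0.01–0.25 °C for indices built from (T, RH) alone but reaches ≈ 0.35 °C
for `wbgt.sun`, whose radiation and wind inputs decouple it most from
*hi*. Real-data threshold tables show gaps of the same sign and size, so
we treat a sub-0.3 °C agreement as a property of tightly coupled indices,
not of the procedure.

# Warning events

Hourly index values are aggregated to daily maxima in local *standard*
time, a fixed UTC offset (default +1 h) with no daylight-saving
arithmetic: daily maxima are afternoon events and insensitive to a
one-hour shift, and a fixed offset keeps day boundaries reproducible. A
day is retained only if at least 18 of its 24 hourly values are present —
a short day cannot be trusted to contain the true maximum — and a dropped
day deliberately breaks runs of consecutive warning days (conservative:
gaps never join two events into one). Warning periods are maximal runs of
at least three consecutive warning days, categorized 3-day, 4-day and
5-plus-day; the level-4 rule (93 °F, five days) runs through the same
machinery by changing the cutoff and minimum length.

# Agreement metrics

*Single-day match*: 100·|official ∩ alternative| / |official| over the
whole record, computed under site-specific thresholds so both systems
flag equally many days (which also makes the metric symmetric).

*Hit rate* per duration category: the number of alternative periods
overlapping (≥ 1 shared day) official periods of that category, divided
by the number of official periods in the category. Two conventions
circulate: counting overlapping *alternative* periods (which can exceed
100 % when several alternative events hit one official event) or counting
*captured official* periods (bounded by 100 %). The 200 %-style worked
cases require the former, so it is the reported `hit_rate`; the captured
convention is computed alongside as `hit_rate_captured`, and an
alternative period overlapping official events of two categories
contributes to both, since contribution is per overlap pair. A category
with no official events carries an explicit marker (the asterisk in
report printouts), never a 0 or 100.

*Quality of hit(s)*: for each overlap pair, 100·(shared days)/(official
period length); the category value is the mean over pairs. Every pair
shares at least one day, so all contributions are positive; an empty
category reports missing, not zero. *False alarms* — alternative periods
overlapping no official period — are counted as a supplementary column
rather than folded into either headline metric. Spatial summaries of
match percentages are unweighted means over stations.

The *response surface* operation evaluates one index along a grid of one
input with the others frozen and summarizes sensitivity as the
least-squares slope. At a warm base point (30 °C, 50 % RH, 1 m/s) the
wet bulb's humidity slope (≈ 0.17 °C/%) exceeds the simplified WBGT's
(≈ 0.166 °C/%), which is the mechanistic reason the two indices agree
with the heat index to such different degrees.

# The synthetic generator

`generate_station()` builds hourly (ta, rh, ws, rad) as: seasonal cosine
(annual mean 10 °C, half-range 9.5 °C, peak 19 July) + diurnal cosine
(half-range 5 °C, peak 14:30 local) + a daily AR(1) synoptic anomaly
(coefficient 0.7, innovation sd 1.8 °C) + additive block boosts for
summer heat episodes (Poisson 1.5 per June–August, mean length 4 days,
boost 9 °C, each episode flagged moist or dry so humidity-sensitive and
humidity-insensitive indices can be driven apart on purpose). Humidity is
a base level (72 %) minus 2.5 %/°C times the diurnal anomaly, minus a
synoptic term, plus noise, clipped to [5, 100] %; an optional moist-mode
day weight produces the bimodal humidity distributions seen at lake-side
stations. Radiation follows a half-sine daylight arc scaled by season and
damped by humidity-linked cloudiness (exactly zero at night); wind is
lognormal. These defaults were chosen once to mimic a Swiss lowland
station and produce a realistic handful (≈ 5) of official warning days
per year; `calibrate_to_warning_rate()` adjusts the episode boost by
bisection when a specific rate is wanted. All randomness belongs to the
generator: one master seed derives per-station substreams
(seed + 104729·i), so every downstream result is bit-reproducible.

What the generator does *not* emulate: spatial correlation between
stations (stations are independent), elevation and topographic effects,
radiation tied to the actual solar ephemeris (the daylight arc is
idealized, while `wbgt.sun` uses the true zenith angle — the two are
consistent enough for screening but not for radiative closure), and
observation gaps or instrument changes. Passing tests therefore
demonstrate the correctness of the *methodology* on data with the right
statistical structure, not the reproduction of any real station's
warning record.

# Problem sizes and test design

The suite's heavyweight fixture is a homogeneous network of 20 stations ×
10 years (≈ 1.75 million hours, all nine indices), built once per test
run and cached; it backs the frequency-preservation and
threshold-consistency checks. Matching metrics are verified against
brute-force day-by-day enumeration on hundreds of randomized 60-day
instances, and the order-statistic threshold against an exhaustive
candidate scan on series up to length 50. Closed-form indices are checked
to 10⁻¹⁰ °C against independently computed frozen values; iterative
solvers against an independently coded dense-grid root scan of the same
balance at 3·10⁻³ °C.

# Known limitations

- The shade/sun WBGT consistency and the region-wide/site-mean threshold
  agreement both degrade in regimes (dry air; weakly *hi*-coupled
  indices) where the underlying approximations genuinely differ; see the
  sections above.
- Thresholds assume a stationary climate over the record; trend-aware
  calibration is out of scope.
- No epidemiological (mortality-based) thresholds: the package compares
  meteorological warning systems to one another, not to health outcomes.
- Forecast verification proper (lead times, CSI/Heidke skill scores) is
  out of scope; the metrics here are the retrospective match statistics.
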