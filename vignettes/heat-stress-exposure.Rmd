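---
title: "Heat stress exposure from in-situ sensor networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat stress exposure from in-situ sensor networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatexposure)
```

## The problem

Dense, low-income urban neighbourhoods experience combinations of heat and
humidity that regional weather stations do not resolve. This package turns
raw records from a network of small temperature/humidity loggers — five
shielded outdoor loggers per settlement plus six temperature-only loggers
per monitored house (three sampling hourly, three two-hourly) — into two
heat-stress metrics:

* **Wet bulb temperature (TW)** — the temperature air reaches when cooled
  to saturation by evaporation; the standard combined heat–humidity metric,
  with 35 °C the commonly cited physiological survivability limit.
* **Wet bulb globe temperature (WBGT)** — the occupational index
  $0.7\,T_{nwb} + 0.2\,T_g + 0.1\,T_a$ outdoors, combining the natural wet
  bulb $T_{nwb}$, the 150 mm black-globe temperature $T_g$ and the air
  temperature $T_a$; compared against ISO 7243 reference limits per
  metabolic work class (25, 28, 30 and 33 °C for heavy work,
  moderate/light work, light work and resting).

All local-time operations (day/night windows, daily maxima) use a fixed
UTC+8 civil clock with no daylight saving.

## Psychrometric core

Saturation vapour pressure uses the Magnus form with Alduchov–Eskridge
coefficients, $e_s(T) = 6.1094\exp(17.625\,T/(243.04+T))$ hPa. It is
accurate to well under 0.1 % over 0–50 °C and, crucially, invertible in
closed form, which gives an exact dew point
$T_d(e) = 243.04\,\ln(e/6.1094) / (17.625 - \ln(e/6.1094))$ and exact
round-trip identities between RH, vapour pressure and dew point that the
test-suite asserts.

TW comes from the Stull (2011) closed-form approximation at standard
sea-level pressure (1013 hPa; the study settlements lie 1–19 m above sea
level, so no pressure correction is applied, though pressure remains a
parameter of the iterative solver for testability):

$$T_W = T\arctan(0.151977\sqrt{RH+8.313659}) + \arctan(T+RH) -
  \arctan(RH-1.676331) + 0.00391838\,RH^{3/2}\arctan(0.023101\,RH) -
  4.686035$$

Two rules surround it. Where RH exceeds 99 % the air is treated as
saturated and TW is set equal to the dry bulb, exactly. Inputs outside the
stated validity rectangle ($T \in [-20, 50]$ °C, $RH \in [5, 99]$ %) are
flagged (`NA`) or raise an error, by configuration; flagged records are
carried through the pipeline, never silently dropped.

### The accuracy oracle and what the 0.3 °C bound means

`thermodynamic_wet_bulb()` is an independent solver of the psychrometric
balance $e_s(T_w) - e = \gamma P (T - T_w)$ with the Assmann coefficient
$\gamma = 6.66\times10^{-4}\,\mathrm{K^{-1}}$ (configurable), by bisection
on the guaranteed bracket $[T_d, T]$ to 0.001 °C. Bisection is chosen over
Newton precisely because the bracket makes convergence unconditional and
deterministic.

`scripts/acceptance.R` measures the mean absolute difference between the
closed form and this solver over the dense grid
$T = -20..50$ °C (step 0.5) $\times$ $RH = 5..99$ % (step 1). Two facts
matter when reading that number. First, the closed form is an empirical
fit whose author excluded the cold-and-dry corner from its claimed domain;
over the full rectangle the disagreement concentrates exactly there (and
in the hot-dry corner), and the grid mean consequently sits above the
0.3 °C often quoted for the fit's own validity region. Second, over the
tropical conditions this pipeline actually meets (roughly 15–40 °C and
RH above 30 %), the two routes agree to well under 0.3 °C, which the test
suite asserts directly. We deliberately report the full-rectangle figure
rather than a region that would flatter it.

The same corner is why the monotonicity property test samples
$T \ge 0$ °C: the empirical fit is provably non-monotone in RH below that,
another signature of the excluded region.

## WBGT models

**Indoors / full shade (Bernard).** The psychrometric wet bulb is computed
from temperature and dew point with the thermodynamic solver, converted to
a natural wet bulb with Bernard's low-air-speed relation
$T_{nwb} = T_a - C(v)(T_a - T_{pwb})$, $C(v) = 0.96 + 0.069\log_{10} v$
for $0.3 \le v < 3$ m/s (and $T_{nwb} = T_{pwb}$ above 3 m/s), at the
fixed indoor air speed of 1 m/s, where $C = 0.96$. The combination uses
Bernard's own shaded weighting $0.67\,T_{nwb} + 0.33\,T_a$ rather than
the ISO 0.7/0.3 split — the two differ by at most a few hundredths of a
degree at indoor humidities, and 0.67/0.33 is the form the cited model
actually validates. Under shade the globe carries no radiant excess and
is reported equal to the air temperature.

**Outdoors (Liljegren).** The globe and wick energy balances are solved by
damped fixed-point iteration (damping 0.9, tolerance 0.02 °C, cap 50
iterations; non-convergence is an error that echoes the offending inputs).
All internal constants are the source's published values: 0.0508 m globe
with emissivity 0.95 and albedo 0.05, 7 mm × 25.4 mm wick with emissivity
0.95 and albedo 0.4, surface emissivity 0.999 and albedo 0.45,
atmospheric emissivity $0.575\,e^{1/7}$. When only global horizontal
irradiance is given, the direct-beam fraction comes from the source's
clearness-index parameterization (capped at 0.9, zero below the horizon).
Night-time records (zenith > 90°) set the solar load to zero rather than
erroring, because loggers run continuously. Irradiance is capped at the
top-of-atmosphere value for the given zenith.

**Solar geometry.** Zenith angles use the low-precision Astronomical
Almanac ephemeris (declination and equation of time from the mean solar
longitude), verified in the tests against an independent Fourier-series
ephemeris to within half a degree. Scenario calculations fix the zenith at
12:00 local on a mid-study reference date (1 March) at the mean settlement
coordinates (5.13° S, 119.42° E); the date is configurable because
"midday" does not pin one down, though equatorial midday zenith varies
little.

**Scenarios.** The four default combinations bracket outdoor daytime
exposure: full shade at 10 m/s, 400 W/m² at 3 m/s, 1000 W/m² at 10 m/s,
1000 W/m² at 1 m/s. Shaded scenarios route through the Bernard model at
the scenario wind. One ordering subtlety is worth recording: at
near-overhead equatorial sun the 400 W/m² + 3 m/s scenario produces
*slightly higher* WBGT than 1000 W/m² + 10 m/s, uniformly across records.
This is genuine model behaviour, not an artifact — near $\cos z = 1$ the
sphere's direct-beam view factor term $f_{dir}(1/(2\cos z) - 1)$ is
negative, and the 1000 W/m² scenario is mostly direct beam (high clearness
index) while 400 W/m² is mostly diffuse, so strong wind at high sun cools
the globe below the moderately sunlit, lightly ventilated case. Intuition
ordering the scenarios purely by irradiance fails here.

## The sensor pipeline

**Percentile adjustment.** Even shielded loggers read high under direct
sun. For each timestamp within each group — by default a settlement ×
placement class (houses pooled separately from outdoor loggers), with a
city-wide pooling mode behind a switch for sensitivity checks — values
above the group's 95th percentile are set to that percentile. The
estimator is the linear-interpolation (type 7) quantile, the default of
the statistical environment the method originates from. Per-settlement
grouping is the default because settlements have distinct microclimates
and retrieval periods; pooling city-wide would systematically cap the
warm settlements.

A consequence of the interpolated estimator deserves a note: capping above
an interpolated quantile alters the top order statistics, so re-running
the adjustment on already-adjusted data lowers the quantile slightly and
caps again. Exact idempotence of the operation holds only when
$(n-1)q$ is an integer for the group size $n$ (21, 41, 61, …) — never for
this network's groups of 5 outdoor loggers. An order-statistic quantile
would be idempotent but caps nothing at all in groups of five, which would
defeat the adjustment's purpose entirely. We keep the interpolated
estimator; the residual second-pass movement is bounded by the spacing of
the top order statistics (about a tenth of a degree at this network's
noise level).

**Downstream stages.** House temperatures are averaged per hour over
whichever of the six loggers reported (two-hourly members contribute to
alternate hours at their native cadence; no interpolation). Humidity is
measured outdoors only, so vapour pressure is computed per RH-bearing
outdoor logger, reduced to a settlement-hour median (even counts take the
midpoint), and applied back to every unit's own adjusted temperature:
$RH = 100\,e/e_s(T_{adj})$ capped at 100 % (the cap absorbs the
supersaturation the homogenization can imply at the coolest unit of an
hour), dew point from the Magnus inverse, floored at the unit's own
temperature for the WBGT models. Settlement-hours lacking either
temperature or humidity coverage are dropped for all units of that
settlement, with all attrition counted in the processing report.

## Exposure statistics

**Exceedance runs.** A run is a maximal continuous period in which every
*observed* WBGT value meets the threshold. Gaps of *missing* records up to
2 hours are bridged — the allowance exists to accommodate stretches where
only two-hourly data were recovered — but an observed below-threshold
record always terminates a run, even inside the window: the bridge
compensates sampling cadence, not cool interludes. Run duration counts
clock hours (end − start + 1 recording hour), so bridged hours count;
`n_records` counts only observed above-threshold records. The detector is
validated against a brute-force enumerator on a thousand random gappy
series, and two structural invariants are asserted: runs at a higher
threshold nest inside runs at any lower one, and every above-threshold
record belongs to exactly one run.

**Daily maxima** are taken per unit on the local calendar date, ties
resolved to the earliest record of the day. The **day window** defaults to
06:00–18:00 local; the boundary is a package choice (equatorial daylight
is nearly constant twelve hours), made configurable.

**Station comparison** pairs each day's in-situ maximum with the same-day
station-side maximum — by default the maximum across stations, with
per-station pairings also reported — and returns the per-day differences
and their mean; unmatched days are excluded and counted.

## Weather stations

The primary dialect is ISD-Lite fixed-width text (self-contained,
whitespace-separated, tenths-of-degree integers, −9999 sentinels); the
full ISD mandatory section is supported read-only, with temperature and
dew point at the documented character positions and their one-character
quality codes. "Passed all quality control checks" maps to the code set
{1, 5}; the filter additionally enforces dew point ≤ temperature and
plausibility bounds of −30–60 °C, counts every removal by reason, and is
idempotent. Sub-hourly records are averaged field-wise into clock-hour
bins. Station TW uses exactly the in-situ machinery (RH recovered from
dew point, Stull form, saturation rule), and timestamps convert from UTC
to the fixed +08:00 civil clock before daily grouping.

## The synthetic network

The generator exists to give every pipeline stage a known truth, so its
process model is deliberately simple rather than physical: a sinusoidal
diurnal cycle (amplitude 3.5 °C peaking at 14:00) over a slow seasonal
drift, fixed per-settlement offsets spanning ±0.8 °C, and a smooth
vapour-pressure cycle shared within each settlement. Houses transform the
outdoor signal with amplitude damping 0.5, a 3-hour phase lag and a
+0.5 °C warm bias — parameters chosen to reproduce the qualitative
day/night inversion (houses cooler than outdoors by day, warmer at night)
rather than any measured building physics. The default climate (mean
28 °C, vapour pressure around 26 hPa) is a tropical coastal wet season
with night-time RH in the mid-90s; occasional noise-driven supersaturation
is intended, as it exercises the saturation rule.

Observation noise is Gaussian (SD 0.3 °C, within consumer-logger
accuracy); outdoor loggers report RH computed from the true vapour
pressure and their own noisy temperature, houses report temperature only.
Contamination adds strictly positive truncated-normal spikes
(mean +3 °C) to 2 % of outdoor daytime records — inside the 5 % headroom
of the 95th-percentile cap, so the adjustment invariant (adjusted closer
to truth than raw at contaminated records) is exactly testable.
Missingness removes random 6-hour blocks from 5 % of unit-days. Stations
read the settlement-mean truth minus a configurable offset (default
1.3 °C, on the temperature scale) at a configurable cadence, with a
fraction of records carrying failing QC codes.

All randomness derives from one seed through fixed per-unit sub-streams,
so adding a unit never perturbs another unit's draws and regression tests
stay stable.

What passing tests on this generator do *not* show: recovery under
correlated sensor drift, non-sinusoidal weather (fronts, rain cooling),
humidity heterogeneity within a settlement (the pipeline itself assumes
settlement-homogeneous vapour pressure), or contamination exceeding the
percentile headroom.

## Problem sizes

The default simulation window is 14 days of the 12-settlement network
(about 200,000 logger records, around 17,000 per settlement), which the
package processes end to end in well under a minute and which gives
threshold-fraction estimates with sampling error far below the ±0.02
recovery tolerance the tests assert. The station-offset recovery test
uses 200 simulated days of paired daily maxima. The analysis scripts under
`analysis/` run the same default window.

## Known limitations

* The Stull form is fit for sea-level pressure; no altitude correction is
  attempted (out of scope for a coastal study area).
* No gap-filling or calibration-drift modelling; records are used at their
  native cadence and flags are carried, not imputed.
* The Liljegren implementation follows the published small-globe
  formulation and constants; no alternative mean-radiant-temperature
  indices (UTCI, PET) are provided.
* Wind and solar series must be supplied (constants or per-record
  values); the package does not downscale reanalysis products.
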