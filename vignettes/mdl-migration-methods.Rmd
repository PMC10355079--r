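---
title: "Methods: from MDL streams to flights, positions and optimal-migration predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from MDL streams to flights, positions and optimal-migration predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdltools)
```

This vignette documents the models and procedures implemented in
`mdltools`, the assumptions behind them, the parameters that matter, and
the numerical choices made where the design was genuinely open. The
package analyses two streams produced by miniature multi-sensor data
loggers (MDLs) on migratory shorebirds: 5-minute accelerometer activity
scores, recorded continuously, and light measurements, recorded during
fixed calendar windows.

## 1. Activity segmentation

### The score model

Each 5-min record is the number of *active* outcomes among five 100-ms
accelerometer subsamples, an integer 0–5. Sustained flapping flight
saturates the score near 5; roosting and incubation sit at 0; foraging
produces intermittent low scores. `weighted_hourly_scores()` aggregates a
clock hour's up to twelve records into a weighted score in 0–60 by plain
summation, with absent records contributing 0.

The phrase "sum of the scores weighted by the number of samples" admits a
second reading in which incomplete hours are extrapolated; that variant
(`weighting = "scaled"`, i.e. `sum * 12 / n_records`) is provided behind a
parameter flag, but summation is the default because it alone reproduces
the documented score bounds of exactly 0 and 60 and never manufactures
evidence from missing records.

### From hours to bouts

`segment_activity()` proceeds in three stages:

1. **Candidate clusters** — maximal runs of consecutive hours with
   weighted score ≥ `high_hour_threshold` (default 30, half the maximum;
   the value is deliberately conservative — genuine migratory flight hours
   score far above it, foraging hours far below).
2. **Bridging** (`bridge_low_hours()`) — weighted scores can sag below the
   threshold during a flight, typically in descending flight with reduced
   flapping near the end of a bout. An adjacent sub-threshold hour stays
   *in flight* while it contains no zero scores. When it does contain
   zeros, the zeros of that hour and the following hour are summed
   (missing records counting as zeros): `landing_zero_sum` = 12
   (≥ 1 h of inactivity) declares a landing; a smaller sum keeps the bird
   airborne, which can merge two clusters into one flight. The rule is
   applied symmetrically at bout starts, which the source procedure does
   not forbid; and at most one zero-containing hour is bridged per gap —
   the lookahead examines exactly one following hour, so bridges are not
   chained across longer lulls.
3. **5-min refinement** (`refine_bout()`) — within and around the cluster
   span, the bout runs from the first to the last record scoring
   ≥ `record_flight_score` (default 3; a record at exactly 3 is in
   flight). The boundary search extends beyond the cluster's hour edges
   through contiguous *non-zero* records, because a flight only ends
   where zero scores appear; missing records do not terminate the search
   (they are defined as zeros and *excluded from the duration*, not
   treated as landings), though a gap of ≥ 12 slots (1 h) does. Interior
   records scoring < 3 and missing slots are excluded from `duration_h`
   and reported as `n_low_omitted` / `n_missing_as_zero`, so duration is
   sub-additive in elapsed time with equality exactly when the bout is a
   clean block.

Every inter-flight gap becomes a stopover; gaps whose midpoint falls
outside the migration season windows (defaults 15 Jul–15 Oct and
1 Feb–30 Apr, configurable) and the leading/trailing periods are labelled
residency. Degenerate inputs behave predictably: an empty record stream
yields an empty segmentation; a cluster containing no record ≥ 3 cannot be
refined and is discarded with a message.

## 2. Threshold geolocation

### Twilights

`detect_twilights()` finds threshold crossings (2 lx for MDLs, 5 lx for
conventional geolocators) and interpolates the crossing time between the
straddling samples, by default on the log-lux scale since light rises
near-exponentially through twilight; binary above/below series fall back
to the interval midpoint. Crossings are never interpolated across the gaps
between MDL measurement windows, and days that are entirely above or below
threshold are flagged as polar-type days.

Visual inspection of annotated twilights is replaced by a parameterised
rule (`edit_twilights()`): an event whose time of day deviates by more
than `max_dev_min` (default 45 min) from the median of same-kind events
within ± `window_days` (default 4) is corrected to that median, dropped
when its day already holds a closer same-kind event (the signature of a
spurious pair from artificial light at night), and dropped when it has
fewer than 2 neighbours. Deviations are computed wrap-aware around
midnight.

### Positions

For each sunrise/sunset pair, longitude comes from the solar-noon
midpoint (using the equation of time), latitude from
`cos H = (sin a − sin φ sin δ)/(cos φ cos δ)` with `H` half the day length
as an hour angle and `δ` the declination at local noon. The equation
`A sin φ + B cos φ = C` is solved in closed form. Three degeneracies are
handled explicitly:

* **no solution** (|C| > √(A²+B²)) — latitude undefined, longitude kept;
* **mirror ambiguity** — with the sun angle below the horizon near an
  equinox, a northern and a southern latitude give the same day length.
  The ambiguity is resolved toward `lat_hint` (default 45°, i.e. the
  northern solution, appropriate for Palearctic systems; override for
  southern-hemisphere work);
* **unidentifiability** — at the equinox the day length barely depends on
  latitude at all. A solution where the derivative of the day-length
  relation falls below 0.02 (dimensionless, roughly |δ| ≲ 1°) is flagged
  `lat_defined = FALSE` rather than reported. Latitude errors grow
  smoothly as the declination approaches zero, which the test suite
  checks as a property.

Solar geometry uses the standard NOAA low-accuracy ephemeris (declination
and equation of time from the geometric mean longitude/anomaly, equation
of centre and mean obliquity), accurate to ≤ 0.1° over 1990–2030, without
atmospheric refraction — any constant refraction offset is absorbed by
the calibrated sun angle. All computation is in UTC.

### Calibration

`hill_ekstrom_calibrate()` sweeps candidate sun elevation angles (default
−9° to −1° in 0.1° steps, user-overridable; the bounds bracket the range
plausible for leg-mounted tags) over a known stationary period and
minimises an instability objective: the standard deviation of the defined
daily latitudes plus `lambda` (default 0.5°) per undefined day. The
source procedure asks for "stable latitudes with no systematic concave or
convex shape"; the λ-penalised standard deviation is one concrete
realisation of that qualitative criterion, and the quadratic-trend
diagnostic is exposed separately as `latitude_convexity()` rather than
folded into the argmin. Calibration is most informative when the window
spans days near an equinox, where a wrong angle destabilises latitude
fastest. If no angle yields at least `min_defined` latitudes the
calibration fails loudly (`failed = TRUE`, with a warning) instead of
returning a meaningless argmin. Civil twilight calibration is simply
`sun_angle = -6`; the occasional practice of falling back to −5° when
winter position clusters are implausibly separated is *not* automated —
that judgement is left to the user.

### Stationary periods

`stationary_periods()` replaces visual inspection of longitude plots with
recursive binary segmentation on the longitude series: the best split
(maximal between-segment sum of squares) is accepted when both sides hold
≥ `min_days` (default 3) daily positions and their mean longitudes differ
by ≥ `min_shift_deg` (default 1°). Longitude drives the segmentation
because it is the coordinate that survives the equinoxes. A 2-day visit
between long stays is therefore *not* resolved — consistent with the
≥ 3 day stationary-period definition downstream analyses assume. Period
statistics (mean and SD of latitude/longitude) use defined latitudes
only; a period of all-undefined latitudes keeps its longitude statistics.

## 3. Route metrics

Distances are haversine great-circle distances on a sphere of mean radius
6371 km — the named method of the source analyses; no ellipsoidal
refinement is attempted. The detour index divides the summed leg
distances (breeding site, stationary positions, wintering site) by the
direct breeding-to-wintering distance; it is ≥ 1 up to a 1e-9 numerical
tolerance, and undefined (NA with a warning) when origin equals
destination.

## 4. Optimal-migration models

The flight range equation `Y(f) = c(1 − 1/√(1+f))`, with `c` a composite
coefficient of morphology and energy conversion efficiency (default
15 000 km, a reasonable shorebird value), anchors both models. `f`, `f0`
and `k` are in proportions of lean body mass (`k` per day), `te` in days,
distances in km.

* **Energy minimizer.** `optimal_departure_fuel()` maximizes
  `R(f) = (Y(f) − Y(f0))/f` by bounded golden-section search (tolerance
  1e-7 on `f`, bracket (1e-8, 10)); the test suite verifies the optimum
  against a dense-grid search (step 1e-4) across the whole `f0` grid.
  `n_flights_energy()` divides the distance by `Y(f*)`. The source
  procedure divides without stating a rounding rule; the default here is
  the ceiling — a partial flight still requires a flight — with the raw
  quotient always attached and nearest-integer rounding available.
* **Time minimizer.** `optimal_n_time()` minimises
  `T(n) = n((1/k)(c²/(c − D/n)² − 1) + te)` by exhaustive enumeration
  over integers 1..`n_max` (default 50, with a warning if the boundary is
  hit). Flights are discrete, so the integer minimum is the primary
  answer; ties break toward fewer flights. `D/n ≥ c` is rejected as
  infeasible.

`sweep_energy()` and `sweep_time()` evaluate the optimizers over
parameter grids (distances 500–3500 km by 100; `f0` 0.005–0.1 by 0.005;
`te` 0.1–2 d by 0.1; `k` spanning 0.01–0.04 with 40 grid points) and
return long-format tables with heat-map plot methods.

## 5. The synthetic-data generator

`make_itinerary()` plants the truth: stopover sites on the
origin–destination great circle (default origin the Öland breeding site;
spacing motivated by the ~300 km spacing of suitable intertidal sites
along the European Atlantic coast, with along-track jitter of SD 50 km
and cross-track jitter of SD 20 km), flight durations set by leg distance
at 16 m s⁻¹ airspeed (as recorded for the species) and rounded to the
5-min grid, stopover durations drawn uniformly from 0.5–3 days — the
scale of the observed stopover-duration distribution. Antipodal
endpoints are rejected (the great circle is ambiguous); in-flight
positions are interpolated along the leg at constant ground speed, the
simplest motion model consistent with the data.

`simulate_activity()` mirrors the logger's score construction — five
Bernoulli subsamples per record rather than a direct score draw — with
noise knobs `p_active_rest` (stationary activity), `p_inactive_flight`
(gliding/descent), `p_missing_record` (record loss). All uniform draws
are generated once per slot index from the seed, so changing one noise
probability does not reshuffle the other draws. The truth table carries,
per planted flight, the wall-clock duration, the *recorded* duration
(minus slots lost to record dropout) and the *scored* duration
(additionally minus in-flight records that scored < 3). The last is the
correct oracle for the segmentation's duration bookkeeping, because the
duration rule excludes sub-3 records by design; wall-clock boundaries
remain the oracle for boundary recovery on noiseless streams.

`simulate_light()` puts the light above threshold exactly when the solar
elevation at the true position exceeds the nominal sun angle, with an
exponential lux ramp (slope 1.4 per degree of elevation, the scale of
real twilight light curves) so that interpolation-based twilight
detection can be exercised realistically, optional shading
(`p_shading` forcing samples to zero) and restriction to the MDL
measurement windows (1–20 Aug, 1–10 Dec, 1–10 Feb, 21 Feb–3 Mar).

What the generator does *not* emulate — and what passing tests therefore
cannot show about real data: weather- and fuel-dependent departure
decisions, wind drift in flight times, gradual (non-Bernoulli) shading
from plumage, habitat-dependent twilight error structure, and equipment
failure modes beyond uniform record loss. Recovery rates on synthetic
cohorts are upper bounds on field performance.

## 6. Problem sizes and reproducibility

The validation suite exercises: 20-bird seeded cohorts (noiseless and
noisy) for segmentation recovery; ~40-day stationary light series for
round-trip geolocation accuracy (longitude within 0.3°, latitude within
0.7° away from the equinoxes) and Hill–Ekström recovery (±0.2° on a
−4.5° angle, and a 10-bird sweep across −7° to −3°); the full
31 × 40 × 20 time-model grid against brute-force enumeration; and 1000
random routes for the detour-index bound. These sizes keep the complete
suite under half a minute while leaving every claim tested at full
parameter coverage. All randomness flows through explicit integer seeds;
`run_pipeline()` records seed, parameters and package version in its run
manifest, and rerunning with the same configuration reproduces its output
tables byte for byte.

## Known limitations

* The hour-level landing rule cannot see landings shorter than the
  1-h-of-zeros criterion; very short stopovers (< ~1 h) merge into the
  surrounding flight, as in the source procedure.
* Latitude is unavailable for roughly ±1–2 weeks around each equinox
  (flagged, not imputed), and the mirror ambiguity near equinoxes is
  resolved by a hemisphere hint, not by data.
* The stationary-period change-point detector assumes shifts expressed in
  longitude; a due-north movement at constant longitude would be missed.
* The optimality models assume equal flight steps, constant `k`, and no
  wind; they predict flight *counts*, not routes or schedules.
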