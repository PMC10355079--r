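# mdltools

Reconstructing the migratory process of small shorebirds from miniature
multi-sensor data loggers (MDLs) — tags of ~1.5 g that record a 5-minute
accelerometer activity score and, during programmed calendar windows, light
levels. From these two streams the package recovers *how a migration was
executed*: how many flights, how long each flight and stopover lasted, where
the bird wintered, how far it flew — and compares the observed division of
migration into flights and stopovers with the predictions of optimal
migration theory.

It is written for movement ecologists working with accelerometer/light
biologging data on short- to medium-distance migrants (the motivating system
is a common ringed plover *Charadrius hiaticula* population breeding in
southern Sweden, migrating ~1300–3000 km to the European Atlantic seaboard).

## What the package computes

**Flight/stopover segmentation from activity scores.** Each 5-min record is
an activity score 0–5 (five binary subsamples). Hourly weighted scores
(sum of the hour's twelve scores, range 0–60) above a threshold (default
≥ 30) mark candidate flight hours; clusters of such hours are extended over
sub-threshold hours that contain no zero scores, a landing being declared
when the zeros of a sub-threshold hour plus the following hour reach 12
(≥ 1 h of inactivity). Bout boundaries are then refined to 5-min resolution,
and records scoring < 3 inside a bout are excluded from the flight duration.

**Threshold light-level geolocation.** Twilights are the times the light
series crosses a lux threshold (2 lx for MDLs, 5 lx for conventional
geolocators). Longitude follows from the solar-noon midpoint of a
sunrise/sunset pair; latitude from the day-length relation
`cos H = (sin a − sin φ sin δ)/(cos φ cos δ)`, where `a` is the sun
elevation angle corresponding to the threshold. `a` is either fixed at −6°
("civil twilight calibration") or estimated by Hill–Ekström calibration:
sweeping candidate angles in 0.1° steps over a known stationary period and
choosing the angle that stabilises the latitude series. Daily positions are
averaged over stationary periods (≥ 3 days) found by change-point
segmentation of the longitude series.

**Route metrics.** Haversine great-circle distances, summed route length
over stationary sites, and the detour index (route / direct distance).

**Optimal migration models.** With the flight range equation
`Y(f) = c (1 − 1/√(1+f))` (default `c` = 15 000 km):

* *energy minimizer* — departure fuel `f*` maximizes distance per unit fuel
  `R(f) = (Y(f) − Y(f0))/f` given a search/settling energy cost `f0`;
  the number of flights for a migration of `D` km is `⌈D / Y(f*)⌉`;
* *time minimizer* — the integer `n` minimizing the total migration time
  `T(n) = n((1/k)(c²/(c − D/n)² − 1) + tₑ)` for fuel deposition rate `k`
  (per day) and search/settling time cost `tₑ` (days).

**Synthetic MDL data.** Because raw tag data are rarely redistributable, the
package ships a ground-truthed generator that emulates the logger's sampling
routine: a migration itinerary on the great circle with planted flights
(airspeed 16 m s⁻¹), 5-min activity records built from five Bernoulli
subsamples, light series driven by the solar elevation at the bird's true
(interpolated) position, restricted to the MDL measurement windows, with
noise knobs for rest-time activity, in-flight inactivity, missing records
and sensor shading. Every downstream stage is validated against this truth.

## Worked example

```r
library(mdltools)

# a synthetic autumn migration: Öland -> Iberia with 3 stopovers
it <- make_itinerary(destination = c(36, -6), n_stopovers = 3, seed = 1)
it
#> MDL synthetic itinerary (autumn, seed 1)
#>   5 sites, 4 flights, total route 2810 km

# a realistically noisy activity log, segmented into bouts
act <- simulate_activity(it, noise = mdl_noise(p_active_rest = 0.05,
                                               p_inactive_flight = 0.02,
                                               p_missing_record = 0.01))
seg <- segment_activity(act)
seg
#> MDL activity segmentation: 4 flight bout(s), 3 stopover(s)
#>   total flight time 48.42 h, longest flight 13.08 h
summary(seg)
#>   n_flights total_flight_h median_flight_h longest_flight_h n_stopovers
#> 1         4       48.41667          12.125         13.08333           3

# sun-angle calibration for a stationary bird observed across the equinox
lt <- simulate_light(c(40, -5), sun_angle = -4.5,
                     start = as.POSIXct("2019-09-01", tz = "UTC"),
                     end   = as.POSIXct("2019-10-10", tz = "UTC"))
hill_ekstrom_calibrate(detect_twilights(lt, threshold = 2))
#> Hill-Ekstrom calibration: sun angle -4.5 deg (objective 2.752)

# optimal-migration predictions for a 3000 km / 2000 km migration
optimal_n_time(D = 3000, k = 0.02, te = 1)   # 3 flights
n_flights_energy(2000, f0 = 0.005)           # 4 flights (quotient 3.25)
```

The four recovered bouts match the planted flights; the Hill–Ekström sweep
recovers the simulated sun angle exactly; and the model predictions say a
time minimizer fueling at 2% of lean mass per day should split a 3000 km
migration into three flights, while an energy minimizer with a very low
settling cost should cross 2000 km in 3–4 short hops.

`run_pipeline()` chains all stages for a synthetic cohort and writes
per-stage CSV tables plus a JSON manifest.

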