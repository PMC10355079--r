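#' @keywords internal
.deg2rad <- pi / 180

# Julian centuries since J2000.0 from a POSIXct (UTC) time
.julian_century <- function(time) {
  jd <- as.numeric(time) / 86400 + 2440587.5
  (jd - 2451545) / 36525
}

#' Solar declination and equation of time
#'
#' Low-precision solar ephemeris following the NOAA solar calculator
#' algorithm (geometric mean longitude/anomaly, equation of centre, apparent
#' longitude corrected for nutation, mean obliquity). Accuracy is better than
#' 0.1 degrees in declination and about 0.1 min in the equation of time over
#' 1990--2030, which is ample for threshold light-level geolocation.
#'
#' @param time POSIXct time(s), UTC.
#' @return A list with components `declination` (degrees) and `eqtime`
#'   (equation of time, minutes; positive when the sun is ahead of clock time).
#' @export
solar_position <- function(time) {
  t <- .julian_century(time)
  L0 <- (280.46646 + t * (36000.76983 + t * 0.0003032)) %% 360
  M <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  e <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  Mr <- M * .deg2rad
  C <- sin(Mr) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * Mr) * (0.019993 - 0.000101 * t) +
    sin(3 * Mr) * 0.000289
  omega <- (125.04 - 1934.136 * t) * .deg2rad
  lambda <- (L0 + C - 0.00569 - 0.00478 * sin(omega)) * .deg2rad
  eps0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) / 60) / 60
  eps <- (eps0 + 0.00256 * cos(omega)) * .deg2rad
  decl <- asin(sin(eps) * sin(lambda)) / .deg2rad
  y <- tan(eps / 2)^2
  L0r <- L0 * .deg2rad
  eqtime <- 4 / .deg2rad *
    (y * sin(2 * L0r) - 2 * e * sin(Mr) + 4 * e * y * sin(Mr) * cos(2 * L0r) -
       0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * Mr))
  list(declination = decl, eqtime = eqtime)
}

#' Solar elevation angle
#'
#' Elevation of the sun's centre above the horizon, without atmospheric
#' refraction (threshold geolocation calibrates an effective sun angle, so an
#' explicit refraction term would be absorbed by the calibration anyway).
#'
#' @param time POSIXct time(s), UTC.
#' @param lat,lon Observer position, decimal degrees (longitude east-positive).
#' @return Elevation in degrees, in \[-90, 90\]. Vectorised over all arguments.
#' @export
#' @examples
#' solar_elevation(as.POSIXct("2020-03-20 12:07:00", tz = "UTC"), 0, 0)
solar_elevation <- function(time, lat, lon) {
  sp <- solar_position(time)
  mins <- (as.numeric(time) / 60) %% 1440
  tst <- (mins + sp$eqtime + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * .deg2rad
  latr <- lat * .deg2rad
  dr <- sp$declination * .deg2rad
  x <- sin(latr) * sin(dr) + cos(latr) * cos(dr) * cos(ha)
  asin(pmin(1, pmax(-1, x))) / .deg2rad
}
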