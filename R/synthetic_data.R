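#' Default breeding-site coordinates (southern Oland, Sweden)
#'
#' Decimal-degree coordinates of the study population's breeding site, used
#' as the default itinerary origin.
#' @export
ottenby <- c(lat = 56.2328, lon = 16.4111)

#' MDL light-measurement windows
#'
#' The logger firmware only records light during fixed calendar windows
#' covering the main migratory and wintering periods. Each element is a
#' `c(month-day start, month-day end)` pair.
#' @export
mdl_light_windows <- list(
  august = c("08-01", "08-20"),
  december = c("12-01", "12-10"),
  february = c("02-01", "02-10"),
  spring = c("02-21", "03-03")
)

#' Noise specification for the synthetic MDL generator
#'
#' Knobs emulating real logger imperfection. All probabilities in \[0, 1\];
#' the default is a noiseless logger.
#'
#' @param p_active_rest Probability that a 5-min subsample taken while the
#'   bird is stationary registers activity (e.g. foraging movement).
#' @param p_inactive_flight Probability that an in-flight subsample registers
#'   no activity (e.g. gliding phases).
#' @param p_missing_record Probability that a whole 5-min record is absent
#'   from the log.
#' @param p_shading Probability that a light sample is shaded to zero
#'   (feather or leg shading of the sensor).
#' @return An object of class `mdl_noise`.
#' @export
mdl_noise <- function(p_active_rest = 0, p_inactive_flight = 0,
                      p_missing_record = 0, p_shading = 0) {
  p <- c(p_active_rest = p_active_rest, p_inactive_flight = p_inactive_flight,
         p_missing_record = p_missing_record, p_shading = p_shading)
  if (any(p < 0 | p > 1)) stop("noise probabilities must lie in [0, 1]")
  structure(as.list(p), class = "mdl_noise")
}

#' Construct a ground-truth migration itinerary
#'
#' Places `n_stopovers` intermediate sites on the origin-to-destination great
#' circle (with configurable along- and cross-track jitter) and schedules the
#' connecting flights, each flight's duration following from its great-circle
#' leg length at a fixed airspeed. The result is the planted truth that
#' [simulate_activity()] and [simulate_light()] turn into logger streams.
#'
#' @param origin,destination `c(lat, lon)` in decimal degrees. Defaults:
#'   the breeding site ([ottenby]) and the Iberian wintering area.
#' @param n_stopovers Number of intermediate stopover sites (>= 0).
#' @param season `"autumn"` or `"spring"`; sets the default departure date.
#' @param seed Integer seed; the itinerary is deterministic given the seed.
#' @param airspeed_ms Flight airspeed in m/s (default 16, as recorded for
#'   the species).
#' @param depart POSIXct departure time from the origin (UTC). Default:
#'   1 Aug 20:00 UTC (autumn) or 25 Feb 20:00 UTC (spring) of 2019/2020.
#' @param stopover_days Length-2 range (days) from which stopover durations
#'   are drawn uniformly.
#' @param jitter_along_km,jitter_cross_km SD of along-track and cross-track
#'   displacement of the intermediate sites, km.
#' @return An object of class `mdl_itinerary`: a list with `sites`
#'   (data.frame: name, lat, lon, arrival, departure), `flights` (data.frame:
#'   from, to, start, end, duration_h, distance_km), and the generator
#'   parameters. Flight times are aligned to the 5-min recording grid.
#' @export
#' @examples
#' it <- make_itinerary(n_stopovers = 3, seed = 1)
#' it$flights$duration_h
make_itinerary <- function(origin = ottenby,
                           destination = c(lat = 36.0, lon = -6.0),
                           n_stopovers = 0,
                           season = c("autumn", "spring"),
                           seed = 1L,
                           airspeed_ms = 16,
                           depart = NULL,
                           stopover_days = c(0.5, 3),
                           jitter_along_km = 50,
                           jitter_cross_km = 20) {
  season <- match.arg(season)
  stopifnot(n_stopovers >= 0, airspeed_ms > 0)
  if (isTRUE(all.equal(unname(origin), unname(destination)))) {
    stop("origin and destination coincide")
  }
  total_km <- haversine(origin[1], origin[2], destination[1], destination[2])
  if (total_km > pi * 6371 * (179 / 180)) {
    stop("antipodal endpoints: great circle is ambiguous")
  }
  if (is.null(depart)) {
    depart <- as.POSIXct(
      if (season == "autumn") "2019-08-01 20:00:00" else "2020-02-25 20:00:00",
      tz = "UTC")
  }
  set.seed(seed)
  if (n_stopovers > 0) {
    frac <- (seq_len(n_stopovers)) / (n_stopovers + 1)
    frac <- frac + stats::rnorm(n_stopovers, 0, jitter_along_km / total_km)
    frac <- pmin(0.98, pmax(0.02, sort(frac)))
    mid <- .gc_interpolate(origin[1], origin[2], destination[1], destination[2],
                           frac)
    # cross-track jitter applied as a latitude/longitude offset of the
    # requested km magnitude (small relative to leg lengths)
    dlat <- stats::rnorm(n_stopovers, 0, jitter_cross_km) / 111.195
    mid[, "lat"] <- pmin(89, pmax(-89, mid[, "lat"] + dlat))
  } else {
    mid <- NULL
  }
  lat <- c(origin[1], if (!is.null(mid)) mid[, "lat"], destination[1])
  lon <- c(origin[2], if (!is.null(mid)) mid[, "lon"], destination[2])
  n_sites <- length(lat)
  leg_km <- haversine(lat[-n_sites], lon[-n_sites], lat[-1], lon[-1])
  # durations rounded to the 5-min recording grid so planted bouts are exact
  dur_h <- round((leg_km / (airspeed_ms * 3.6)) * 12) / 12
  dur_h <- pmax(1 / 12, dur_h)
  stop_d <- stats::runif(n_sites - 2, stopover_days[1], stopover_days[2])

  arrival <- departure <- rep(depart, n_sites)
  start <- end <- rep(depart, n_sites - 1)
  t <- .align5(depart)
  for (i in seq_len(n_sites - 1)) {
    departure[i] <- t
    start[i] <- t
    t <- t + dur_h[i] * 3600
    end[i] <- t
    arrival[i + 1] <- t
    if (i < n_sites - 1) t <- .align5(t + stop_d[i] * 86400)
  }
  departure[n_sites] <- arrival[n_sites] + 120 * 86400  # residency
  sites <- data.frame(
    name = c("origin", if (n_sites > 2) paste0("stop", seq_len(n_sites - 2)),
             "destination"),
    lat = lat, lon = lon, arrival = arrival, departure = departure)
  flights <- data.frame(
    from = seq_len(n_sites - 1), to = seq_len(n_sites - 1) + 1,
    start = start, end = end, duration_h = dur_h, distance_km = leg_km)
  structure(list(sites = sites, flights = flights, airspeed_ms = airspeed_ms,
                 season = season, seed = seed),
            class = "mdl_itinerary")
}

# snap a time down to the 5-min grid
.align5 <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 300) * 300,
             origin = "1970-01-01", tz = "UTC")
}

#' @export
print.mdl_itinerary <- function(x, ...) {
  cat("MDL synthetic itinerary (", x$season, ", seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  %d sites, %d flights, total route %.0f km\n",
              nrow(x$sites), nrow(x$flights), sum(x$flights$distance_km)))
  print(x$sites[, c("name", "lat", "lon")], ...)
  invisible(x)
}

#' True position of the bird at given times
#'
#' Stationary at the occupied site outside flights; during a flight the
#' position is interpolated along the great-circle leg at constant ground
#' speed.
#'
#' @param itin An `mdl_itinerary`.
#' @param times POSIXct vector (UTC).
#' @return data.frame with `timestamp_utc`, `lat`, `lon`.
#' @export
itinerary_position <- function(itin, times) {
  s <- itin$sites
  f <- itin$flights
  lat <- rep(NA_real_, length(times))
  lon <- rep(NA_real_, length(times))
  # site occupancy: site i between arrival[i] and departure[i]
  occ <- rep(nrow(s), length(times))
  for (i in rev(seq_len(nrow(s)))) occ[times < s$departure[i]] <- i
  lat <- s$lat[occ]
  lon <- s$lon[occ]
  for (i in seq_len(nrow(f))) {
    in_f <- times >= f$start[i] & times < f$end[i]
    if (any(in_f)) {
      frac <- as.numeric(times[in_f] - f$start[i], units = "secs") /
        as.numeric(f$end[i] - f$start[i], units = "secs")
      p <- .gc_interpolate(s$lat[f$from[i]], s$lon[f$from[i]],
                           s$lat[f$to[i]], s$lon[f$to[i]], frac)
      lat[in_f] <- p[, "lat"]
      lon[in_f] <- p[, "lon"]
    }
  }
  data.frame(timestamp_utc = times, lat = lat, lon = lon)
}

#' Simulate an MDL activity-score stream
#'
#' Emulates the logger's sampling routine: one record per 5-min slot, each
#' record the sum of 5 binary activity subsamples. During planted flights a
#' subsample is active with probability `1 - p_inactive_flight`; outside
#' flights with probability `p_active_rest`. Whole records are dropped with
#' probability `p_missing_record`. The underlying uniform draws are generated
#' once per slot index from the seed, so changing a noise probability does
#' not reshuffle the other draws.
#'
#' @param itin An `mdl_itinerary` giving the planted flight intervals.
#' @param noise An [mdl_noise()] specification.
#' @param start,end POSIXct bounds of the recording (UTC). Defaults: 2 days
#'   before the first flight to 2 days after the last.
#' @param seed Integer seed (default: the itinerary's seed).
#' @return data.frame with columns `timestamp_utc` (slot start), `score`
#'   (0-5), `n_subsamples` (always 5). Attribute `"truth"` holds the planted
#'   flight table plus two observability columns: `recorded_duration_h`, the
#'   planted duration minus slots lost to `p_missing_record` (what the
#'   logger could measure), and `scored_duration_h`, additionally excluding
#'   in-flight records that scored below 3 (what the flight-duration rule,
#'   which omits such records by design, can recover from the stream).
#' @export
simulate_activity <- function(itin, noise = mdl_noise(), start = NULL,
                              end = NULL, seed = itin$seed) {
  stopifnot(inherits(itin, "mdl_itinerary"), inherits(noise, "mdl_noise"))
  f <- itin$flights
  if (is.null(start)) start <- .align5(min(f$start) - 2 * 86400)
  if (is.null(end)) end <- .align5(max(f$end) + 2 * 86400)
  stopifnot(start < end)
  slots <- seq(.align5(start), end - 300, by = 300)
  n <- length(slots)
  in_flight <- rep(FALSE, n)
  for (i in seq_len(nrow(f))) {
    in_flight <- in_flight | (slots >= f$start[i] & slots < f$end[i])
  }
  set.seed(seed)
  u_sub <- matrix(stats::runif(n * 5), n, 5)
  u_miss <- stats::runif(n)
  p_active <- ifelse(in_flight, 1 - noise$p_inactive_flight,
                     noise$p_active_rest)
  score <- as.integer(rowSums(u_sub < p_active))
  keep <- u_miss >= noise$p_missing_record
  rec <- data.frame(timestamp_utc = slots[keep], score = score[keep],
                    n_subsamples = rep(5L, sum(keep)))
  truth <- f
  truth$recorded_duration_h <- vapply(seq_len(nrow(f)), function(i) {
    sum(keep & slots >= f$start[i] & slots < f$end[i]) * 5 / 60
  }, numeric(1))
  truth$scored_duration_h <- vapply(seq_len(nrow(f)), function(i) {
    sum(keep & score >= 3 & slots >= f$start[i] & slots < f$end[i]) * 5 / 60
  }, numeric(1))
  attr(rec, "truth") <- truth
  rec
}

#' Simulate an MDL light stream
#'
#' Light is above the lux threshold iff the solar elevation at the bird's
#' true (interpolated) position exceeds `sun_angle`; around the threshold the
#' lux value follows an exponential ramp in elevation, emulating the steep
#' twilight light curve. Shaded samples are forced to zero.
#'
#' @param x An `mdl_itinerary`, or a fixed site `c(lat, lon)`.
#' @param sun_angle Sun elevation angle (degrees, in \[-18, 6\]) at which the
#'   light crosses the threshold.
#' @param threshold Lux threshold (default 2, the MDL setting).
#' @param sample_interval_min Sampling interval, minutes (>= 1; default 5).
#' @param p_shading Per-sample shading probability.
#' @param start,end POSIXct bounds (UTC); required for a fixed site.
#' @param windows Optional list of `c("mm-dd", "mm-dd")` calendar windows
#'   (e.g. [mdl_light_windows]) restricting output to the MDL measurement
#'   periods.
#' @param lux_slope Steepness of the lux ramp (per degree of elevation).
#' @param seed Integer seed (used only when `p_shading > 0`).
#' @return data.frame with `timestamp_utc`, `lux`, `above` (0/1). Attribute
#'   `"no_crossing_days"`: dates whose samples are all above or all below the
#'   threshold (polar-type days).
#' @export
simulate_light <- function(x, sun_angle = -6, threshold = 2,
                           sample_interval_min = 5, p_shading = 0,
                           start = NULL, end = NULL, windows = NULL,
                           lux_slope = 1.4, seed = 1L) {
  stopifnot(sun_angle >= -18, sun_angle <= 6, sample_interval_min >= 1,
            p_shading >= 0, p_shading <= 1)
  if (inherits(x, "mdl_itinerary")) {
    if (is.null(start)) start <- .align5(min(x$flights$start) - 2 * 86400)
    if (is.null(end)) end <- .align5(max(x$flights$end) + 2 * 86400)
  } else {
    stopifnot(length(x) == 2, !is.null(start), !is.null(end))
  }
  times <- seq(as.POSIXct(start, tz = "UTC"), as.POSIXct(end, tz = "UTC"),
               by = sample_interval_min * 60)
  if (!is.null(windows)) {
    md <- format(times, "%m-%d")
    keep <- Reduce(`|`, lapply(windows, function(w) {
      if (w[1] <= w[2]) md >= w[1] & md <= w[2] else md >= w[1] | md <= w[2]
    }))
    times <- times[keep]
  }
  if (inherits(x, "mdl_itinerary")) {
    pos <- itinerary_position(x, times)
  } else {
    pos <- data.frame(lat = rep(x[1], length(times)),
                      lon = rep(x[2], length(times)))
  }
  elev <- solar_elevation(times, pos$lat, pos$lon)
  lux <- threshold * exp(lux_slope * (elev - sun_angle))
  lux <- pmin(lux, 1e5)
  lux[lux < 1e-4] <- 0
  if (p_shading > 0) {
    set.seed(seed)
    lux[stats::runif(length(times)) < p_shading] <- 0
  }
  out <- data.frame(timestamp_utc = times, lux = lux,
                    above = as.integer(lux > threshold))
  day <- as.Date(times)
  frac_above <- tapply(out$above, day, mean)
  attr(out, "no_crossing_days") <-
    as.Date(names(frac_above)[frac_above %in% c(0, 1)])
  out
}
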