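#' Detect twilight events by threshold crossing
#'
#' Finds the times at which the light series crosses the lux threshold.
#' Crossing times are interpolated between the two straddling samples; by
#' default on the log-lux scale (light rises near-exponentially through
#' twilight), falling back to linear, or to the interval midpoint for binary
#' above/below series.
#'
#' @param light data.frame with `timestamp_utc` and `lux` (or a 0/1 `above`
#'   column), chronological and regularly sampled (gaps between measurement
#'   windows are tolerated; no crossing is reported across a gap).
#' @param threshold Lux threshold (default 2, the MDL setting; conventional
#'   geolocators in this pipeline use 5).
#' @param interpolate `"log"`, `"linear"` or `"midpoint"`.
#' @return data.frame with `time`, `kind` (`"rise"`/`"set"`), `edited`
#'   (FALSE). Attribute `"no_crossing_days"`: dates with samples all above
#'   or all below the threshold (polar-type days).
#' @export
detect_twilights <- function(light, threshold = 2,
                             interpolate = c("log", "linear", "midpoint")) {
  interpolate <- match.arg(interpolate)
  stopifnot(is.data.frame(light), "timestamp_utc" %in% names(light))
  t <- light$timestamp_utc
  stopifnot(!is.unsorted(as.numeric(t)))
  has_lux <- "lux" %in% names(light)
  above <- if (has_lux) light$lux > threshold else light$above > 0
  dt <- diff(as.numeric(t))
  step <- stats::median(dt)
  i <- which(above[-length(above)] != above[-1] &
               dt <= 1.5 * step)  # no crossings across window gaps
  if (length(i) == 0) {
    ev <- data.frame(time = as.POSIXct(character(), tz = "UTC"),
                     kind = character(), edited = logical())
  } else {
    frac <- rep(0.5, length(i))
    if (has_lux && interpolate != "midpoint") {
      l1 <- light$lux[i]
      l2 <- light$lux[i + 1]
      if (interpolate == "log") {
        ok <- l1 > 0 & l2 > 0
        frac[ok] <- (log(threshold) - log(l1[ok])) /
          (log(l2[ok]) - log(l1[ok]))
        frac[!ok] <- (threshold - l1[!ok]) / (l2[!ok] - l1[!ok])
      } else {
        frac <- (threshold - l1) / (l2 - l1)
      }
      frac <- pmin(1, pmax(0, frac))
    }
    ev <- data.frame(
      time = t[i] + frac * (as.numeric(t[i + 1]) - as.numeric(t[i])),
      kind = ifelse(above[i + 1], "rise", "set"),
      edited = FALSE)
  }
  day <- as.Date(t)
  frac_above <- tapply(above, day, mean)
  attr(ev, "no_crossing_days") <-
    as.Date(names(frac_above)[frac_above %in% c(0, 1)])
  ev
}

#' Edit twilight events against neighbouring days
#'
#' Automatic replacement for visual inspection of annotated twilights: an
#' event whose time of day deviates from the median of same-kind events on
#' the surrounding days by more than `max_dev_min` minutes is corrected to
#' that median, or dropped when it has no support (fewer than `min_neighbours`
#' neighbouring events, or its day already holds a closer same-kind event,
#' as for a spurious pair from artificial light at night).
#'
#' @param events Output of [detect_twilights()].
#' @param window_days Half-width of the neighbour window, days (default 4).
#' @param max_dev_min Tolerated deviation, minutes (default 45).
#' @param min_neighbours Minimum same-kind neighbours required (default 2).
#' @return The edited event table; corrected events have `edited = TRUE`.
#' @export
edit_twilights <- function(events, window_days = 4, max_dev_min = 45,
                           min_neighbours = 2) {
  if (nrow(events) == 0) return(events)
  tnum <- as.numeric(events$time)
  mins <- (tnum / 60) %% 1440
  keep <- rep(TRUE, nrow(events))
  for (i in seq_len(nrow(events))) {
    nb <- which(events$kind == events$kind[i] &
                  abs(tnum - tnum[i]) <= window_days * 86400 &
                  seq_len(nrow(events)) != i)
    if (length(nb) < min_neighbours) {
      keep[i] <- FALSE
      next
    }
    # wrap-aware deviation of neighbours' time-of-day from this event
    dev <- ((mins[nb] - mins[i] + 720) %% 1440) - 720
    med <- stats::median(dev)
    if (abs(med) > max_dev_min) {
      # same-kind event on the same day closer to the neighbours? then this
      # one is spurious
      same_day <- nb[abs(tnum[nb] - tnum[i]) < 43200]
      if (length(same_day) > 0) {
        keep[i] <- FALSE
      } else {
        events$time[i] <- events$time[i] + med * 60
        events$edited[i] <- TRUE
      }
    }
  }
  out <- events[keep, ]
  rownames(out) <- NULL
  out
}

#' Daily position from a sunrise/sunset pair
#'
#' Threshold geolocation: longitude from the solar-noon time (the midpoint
#' of the twilight pair), latitude solved numerically from the day-length
#' relation `cos H = (sin a - sin phi sin delta) / (cos phi cos delta)`,
#' with `a` the calibrated sun elevation angle and `delta` the solar
#' declination at local noon.
#'
#' Close to the equinoxes, and with the sun angle below the horizon, the
#' day-length relation can admit two mirror-latitude solutions; the
#' ambiguity is resolved toward `lat_hint` (default: the northern solution).
#' When the relation has no solution, or the solution is numerically
#' unidentifiable (day length almost independent of latitude, as at the
#' equinox), `lat_defined` is FALSE while longitude is still returned.
#'
#' @param rise,set POSIXct twilight times (rise before set, same day).
#' @param sun_angle Calibrated sun elevation angle, degrees (negative below
#'   the horizon; -6 is civil twilight calibration).
#' @param lat_hint Approximate latitude used only to resolve the mirror
#'   ambiguity (default 45, i.e. northern-hemisphere solutions preferred).
#' @return One-row data.frame: `date`, `lat`, `lon`, `lat_defined`.
#' @export
position_from_twilight_pair <- function(rise, set, sun_angle = -6,
                                        lat_hint = 45) {
  len_h <- as.numeric(set, units = "secs") - as.numeric(rise, units = "secs")
  len_h <- len_h / 3600
  if (is.na(len_h) || len_h <= 0 || len_h >= 24) {
    stop("twilight pair must satisfy 0 < set - rise < 24 h")
  }
  noon <- rise + len_h * 1800  # rise + half the day, seconds
  sp <- solar_position(noon)
  mins <- (as.numeric(noon) / 60) %% 1440
  lon <- (720 - mins - sp$eqtime) / 4
  lon <- ((lon + 180) %% 360) - 180
  # solve sin(phi) sin(d) + cos(H) cos(phi) cos(d) = sin(a), i.e.
  # A sin(phi) + B cos(phi) = C, in closed form
  H <- (len_h * 15 / 2) * .deg2rad
  dr <- sp$declination * .deg2rad
  A <- sin(dr)
  B <- cos(H) * cos(dr)
  C <- sin(sun_angle * .deg2rad)
  R <- sqrt(A^2 + B^2)
  lat <- NA_real_
  defined <- FALSE
  if (R > 1e-9 && abs(C / R) <= 1) {
    s <- asin(C / R)
    g <- atan2(B, A)
    cand <- c(s - g, pi - s - g)
    cand <- ((cand + pi) %% (2 * pi)) - pi
    cand <- cand[abs(cand) <= 89.5 * .deg2rad]
    cand <- unique(round(cand, 9))
    if (length(cand) > 0) {
      phi <- if (length(cand) == 1) {
        cand
      } else {
        cand[which.min(abs(cand - lat_hint * .deg2rad))]
      }
      # identifiability guard: near the equinoxes the day length barely
      # depends on latitude and the solution carries no information
      dfdphi <- cos(phi) * A - sin(phi) * B
      if (abs(dfdphi) >= 0.02) {
        lat <- phi / .deg2rad
        defined <- TRUE
      }
    }
  }
  data.frame(date = as.Date(noon), lat = lat, lon = lon,
             lat_defined = defined)
}

#' Daily positions from a twilight series
#'
#' Pairs each sunrise with the following sunset (plausible day lengths only)
#' and applies [position_from_twilight_pair()].
#'
#' @param events Twilight event table ([detect_twilights()], optionally
#'   [edit_twilights()]).
#' @param sun_angle Sun elevation angle, degrees.
#' @param min_len_h,max_len_h Plausible day-length bounds, hours.
#' @param lat_hint Passed to [position_from_twilight_pair()].
#' @return data.frame with one row per day: `date`, `lat`, `lon`,
#'   `lat_defined`.
#' @export
twilight_positions <- function(events, sun_angle = -6, min_len_h = 1,
                               max_len_h = 23, lat_hint = 45) {
  events <- events[order(events$time), ]
  rises <- which(events$kind == "rise")
  out <- list()
  for (i in rises) {
    if (i == nrow(events)) next
    if (events$kind[i + 1] != "set") next
    len <- as.numeric(events$time[i + 1] - events$time[i], units = "hours")
    if (len < min_len_h || len > max_len_h) next
    out[[length(out) + 1]] <-
      position_from_twilight_pair(events$time[i], events$time[i + 1],
                                  sun_angle, lat_hint = lat_hint)
  }
  if (length(out) == 0) {
    return(data.frame(date = as.Date(character()), lat = numeric(),
                      lon = numeric(), lat_defined = logical()))
  }
  do.call(rbind, out)
}

#' Hill-Ekstrom sun-angle calibration
#'
#' Sweeps candidate sun elevation angles (default -9 to -1 degrees in 0.1
#' degree increments) over a known stationary period and selects the angle
#' that stabilises the latitude series: the objective is the standard
#' deviation of the defined daily latitudes plus a penalty of `lambda`
#' degrees per day on which the day-length equation has no solution. Most
#' informative when the window includes days near an equinox, where a wrong
#' angle destabilises latitude fastest.
#'
#' @param events Twilight event table for the stationary period.
#' @param angle_grid Candidate angles, degrees (default `seq(-9, -1, 0.1)`).
#' @param lambda Penalty per undefined day, degrees (default 0.5).
#' @param stationary_window Optional `c(start, end)` Dates restricting the
#'   events used.
#' @param min_defined Minimum defined latitudes for an angle to be scored.
#' @param lat_hint Passed to [position_from_twilight_pair()].
#' @return Object of class `hill_ekstrom`: `sun_angle` (argmin; NA on
#'   failure), `failed`, `objective_curve` (data.frame: angle, objective,
#'   sd_lat, n_undefined), `positions` (daily positions at the selected
#'   angle).
#' @export
hill_ekstrom_calibrate <- function(events, angle_grid = seq(-9, -1, by = 0.1),
                                   lambda = 0.5, stationary_window = NULL,
                                   min_defined = 3, lat_hint = 45) {
  if (!is.null(stationary_window)) {
    d <- as.Date(events$time)
    events <- events[d >= stationary_window[1] & d <= stationary_window[2], ]
  }
  curve <- do.call(rbind, lapply(angle_grid, function(a) {
    pos <- twilight_positions(events, sun_angle = a, lat_hint = lat_hint)
    n_def <- sum(pos$lat_defined)
    n_undef <- nrow(pos) - n_def
    if (n_def < min_defined) {
      data.frame(angle = a, objective = NA_real_, sd_lat = NA_real_,
                 n_undefined = n_undef)
    } else {
      s <- stats::sd(pos$lat[pos$lat_defined])
      data.frame(angle = a, objective = s + lambda * n_undef, sd_lat = s,
                 n_undefined = n_undef)
    }
  }))
  if (all(is.na(curve$objective))) {
    warning("Hill-Ekstrom calibration failed: no angle yields enough ",
            "defined latitudes")
    return(structure(list(sun_angle = NA_real_, failed = TRUE,
                          objective_curve = curve, positions = NULL),
                     class = "hill_ekstrom"))
  }
  best <- curve$angle[which.min(curve$objective)]
  structure(list(sun_angle = best, failed = FALSE, objective_curve = curve,
                 positions = twilight_positions(events, sun_angle = best,
                                                lat_hint = lat_hint)),
            class = "hill_ekstrom")
}

#' @export
print.hill_ekstrom <- function(x, ...) {
  if (x$failed) {
    cat("Hill-Ekstrom calibration: FAILED\n")
  } else {
    cat(sprintf("Hill-Ekstrom calibration: sun angle %.1f deg (objective %.3f)\n",
                x$sun_angle,
                min(x$objective_curve$objective, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
plot.hill_ekstrom <- function(x, ...) {
  graphics::plot(x$objective_curve$angle, x$objective_curve$objective,
                 type = "l", xlab = "sun elevation angle (deg)",
                 ylab = "latitude instability objective", ...)
  if (!x$failed) graphics::abline(v = x$sun_angle, lty = 2)
  invisible(x)
}

#' Latitude-trend convexity diagnostic
#'
#' Quadratic trend coefficient of latitude against day over a stationary
#' period; a systematically concave or convex shape indicates a mis-
#' calibrated sun angle. Exposed as a diagnostic, not part of the
#' calibration objective.
#'
#' @param positions Daily positions (as from [twilight_positions()]).
#' @return The quadratic coefficient (degrees latitude per day squared),
#'   NA when fewer than 5 defined latitudes.
#' @export
latitude_convexity <- function(positions) {
  p <- positions[positions$lat_defined, ]
  if (nrow(p) < 5) return(NA_real_)
  d <- as.numeric(p$date - min(p$date))
  unname(stats::coef(stats::lm(p$lat ~ d + I(d^2)))[3])
}

# best single changepoint (maximal between-segment sum of squares) of x,
# respecting a minimum segment length; returns split index or 0
.best_split <- function(x, min_len) {
  n <- length(x)
  if (n < 2 * min_len) return(0L)
  ks <- min_len:(n - min_len)
  cs <- cumsum(x)
  tot <- cs[n]
  m1 <- cs[ks] / ks
  m2 <- (tot - cs[ks]) / (n - ks)
  gain <- ks * (n - ks) / n * (m1 - m2)^2
  ks[which.max(gain)]
}

#' Stationary periods from daily positions
#'
#' Replaces visual inspection of longitude plots by recursive binary
#' segmentation on the longitude series: a changepoint is accepted when the
#' two sides' mean longitudes differ by at least `min_shift_deg` and both
#' segments hold at least `min_days` daily positions. Periods shorter than
#' `min_days` are discarded.
#'
#' @param positions Daily position table (`date`, `lat`, `lon`,
#'   `lat_defined`), chronological.
#' @param min_days Minimum period length, days (default 3).
#' @param min_shift_deg Minimum mean longitude shift to accept a
#'   changepoint, degrees (default 1).
#' @return data.frame with one row per stationary period: `start`, `end`
#'   (Dates), `n_days`, `mean_lat`, `sd_lat`, `mean_lon`, `sd_lon`. Latitude
#'   statistics are over defined latitudes only (NA when none).
#' @export
stationary_periods <- function(positions, min_days = 3, min_shift_deg = 1) {
  n <- nrow(positions)
  if (n == 0) {
    return(data.frame(start = as.Date(character()), end = as.Date(character()),
                      n_days = integer(), mean_lat = numeric(),
                      sd_lat = numeric(), mean_lon = numeric(),
                      sd_lon = numeric()))
  }
  segment_rec <- function(i, j) {
    x <- positions$lon[i:j]
    k <- .best_split(x, min_days)
    if (k == 0L) return(list(c(i, j)))
    if (abs(mean(x[1:k]) - mean(x[(k + 1):length(x)])) < min_shift_deg) {
      return(list(c(i, j)))
    }
    c(segment_rec(i, i + k - 1), segment_rec(i + k, j))
  }
  segs <- segment_rec(1, n)
  out <- do.call(rbind, lapply(segs, function(s) {
    p <- positions[s[1]:s[2], ]
    lat_ok <- p$lat_defined
    data.frame(start = min(p$date), end = max(p$date), n_days = nrow(p),
               mean_lat = if (any(lat_ok)) mean(p$lat[lat_ok]) else NA_real_,
               sd_lat = if (sum(lat_ok) > 1) stats::sd(p$lat[lat_ok]) else
                 NA_real_,
               mean_lon = mean(p$lon),
               sd_lon = if (nrow(p) > 1) stats::sd(p$lon) else NA_real_)
  }))
  out <- out[out$n_days >= min_days, , drop = FALSE]
  rownames(out) <- NULL
  out
}
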