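#' Segmentation parameters
#'
#' Thresholds of the flight/stopover classification.
#'
#' @param high_hour_threshold Weighted hourly score at or above which an hour
#'   is a candidate flight hour (default 30, i.e. half the maximum of 60).
#' @param record_flight_score Minimum 5-min score counted as flight when
#'   refining bout boundaries and durations (default 3; a record scoring
#'   exactly 3 is in flight).
#' @param landing_zero_sum Number of zero scores summed over a sub-threshold
#'   hour and the following hour at or above which the bird is considered
#'   landed (default 12, corresponding to >= 1 h of inactivity).
#' @param weighting `"sum"`: weighted hourly score is the plain sum of the
#'   hour's up-to-12 scores with absent records contributing 0 (reproduces
#'   the score bounds 0 and 60). `"scaled"`: the sum is rescaled by
#'   12 / n_records, extrapolating incomplete hours.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(high_hour_threshold = 30,
                                record_flight_score = 3,
                                landing_zero_sum = 12,
                                weighting = c("sum", "scaled")) {
  stopifnot(high_hour_threshold > 0, high_hour_threshold <= 60,
            record_flight_score > 0, record_flight_score <= 5,
            landing_zero_sum > 0)
  structure(list(high_hour_threshold = high_hour_threshold,
                 record_flight_score = record_flight_score,
                 landing_zero_sum = landing_zero_sum,
                 weighting = match.arg(weighting)),
            class = "segmentation_params")
}

#' Default migration season windows
#'
#' Calendar windows (month-day) within which inter-flight gaps are labelled
#' stopovers; gaps outside are breeding/winter residency.
#' @export
season_windows <- list(autumn = c("07-15", "10-15"),
                       spring = c("02-01", "04-30"))

#' Weighted hourly activity scores
#'
#' Aggregates the 5-min activity scores (0-5) into one weighted score per
#' clock hour, range 0 (12 zero scores) to 60 (12 scores of 5). Absent
#' records contribute 0 to the sum and are counted as zeros in `zero_count`,
#' consistent with the flight-duration rule for failed subsampling.
#'
#' @param records data.frame with `timestamp_utc` (POSIXct, 5-min aligned,
#'   unique) and `score` (integer 0-5).
#' @param params A [segmentation_params()] object.
#' @return data.frame with one row per clock hour from the first to the last
#'   record: `hour_start`, `weighted_score`, `n_records`, `zero_count`,
#'   `any_zero`.
#' @export
#' @examples
#' h <- as.POSIXct("2019-08-01 00:00", tz = "UTC") + 300 * (0:11)
#' weighted_hourly_scores(data.frame(timestamp_utc = h, score = 5))
weighted_hourly_scores <- function(records, params = segmentation_params()) {
  stopifnot(is.data.frame(records),
            all(c("timestamp_utc", "score") %in% names(records)))
  if (nrow(records) == 0) {
    return(data.frame(hour_start = as.POSIXct(character(), tz = "UTC"),
                      weighted_score = numeric(), n_records = integer(),
                      zero_count = integer(), any_zero = logical()))
  }
  if (anyDuplicated(records$timestamp_utc)) {
    stop("duplicate record timestamps")
  }
  if (any(as.numeric(records$timestamp_utc) %% 300 != 0)) {
    stop("records must be aligned to the 5-min grid")
  }
  if (any(records$score < 0 | records$score > 5)) {
    stop("scores must lie in 0..5")
  }
  hr <- as.POSIXct(floor(as.numeric(records$timestamp_utc) / 3600) * 3600,
                   origin = "1970-01-01", tz = "UTC")
  grid <- seq(min(hr), max(hr), by = 3600)
  idx <- match(hr, grid)
  n_records <- tabulate(idx, nbins = length(grid))
  wsum <- unname(tapply(records$score, factor(idx, levels = seq_along(grid)),
                        sum, default = 0))
  wsum[is.na(wsum)] <- 0
  nzero <- unname(tapply(records$score == 0,
                         factor(idx, levels = seq_along(grid)),
                         sum, default = 0))
  nzero[is.na(nzero)] <- 0
  zero_count <- as.integer(nzero + (12 - n_records))
  weighted <- if (params$weighting == "scaled") {
    ifelse(n_records > 0, wsum * 12 / n_records, 0)
  } else {
    wsum
  }
  data.frame(hour_start = grid, weighted_score = as.numeric(weighted),
             n_records = as.integer(n_records), zero_count = zero_count,
             any_zero = zero_count > 0)
}

#' Clusters of consecutive high-activity hours
#'
#' Maximal runs of consecutive hours whose weighted score reaches the
#' candidate-flight threshold.
#'
#' @param hours Output of [weighted_hourly_scores()] (chronological).
#' @param params A [segmentation_params()] object.
#' @return A list of integer vectors, each the row indices (into `hours`) of
#'   one cluster.
#' @export
find_flight_hour_clusters <- function(hours, params = segmentation_params()) {
  high <- hours$weighted_score >= params$high_hour_threshold
  if (!any(high)) return(list())
  r <- rle(high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mapply(function(s, e) s:e, starts[r$values], ends[r$values],
         SIMPLIFY = FALSE)
}

# Extend one cluster edge outward over sub-threshold hours.
# An adjacent sub-threshold hour with no zero scores stays in flight; an hour
# containing zeros ends the flight when its zeros plus the next (outward)
# hour's zeros reach landing_zero_sum, and is otherwise absorbed. At most one
# zero-containing hour is bridged per gap (no chained bridges).
.extend_edge <- function(edge, dir, hours, params) {
  n <- nrow(hours)
  j <- edge + dir
  bridged_zero <- FALSE
  while (j >= 1 && j <= n) {
    if (hours$weighted_score[j] >= params$high_hour_threshold) {
      bridged_zero <- FALSE
      edge <- j
    } else if (hours$zero_count[j] == 0) {
      edge <- j
    } else {
      if (bridged_zero) break
      k <- j + dir
      z_next <- if (k >= 1 && k <= n) hours$zero_count[k] else 12L
      if (hours$zero_count[j] + z_next >= params$landing_zero_sum) break
      edge <- j
      bridged_zero <- TRUE
    }
    j <- j + dir
  }
  edge
}

#' Bridge sub-threshold hours adjacent to flight-hour clusters
#'
#' Weighted scores can drop below the candidate threshold during a flight
#' (e.g. descending flight with reduced flapping), particularly near its end.
#' A sub-threshold hour adjacent to a cluster remains in flight as long as it
#' contains no zero scores; when it does contain zeros, the zeros of that
#' hour and of the following hour are summed and the flight ends only if the
#' sum reaches `landing_zero_sum`. When bridging joins two clusters the
#' sequence becomes one flight. Applied symmetrically at both bout edges.
#'
#' @param clusters Output of [find_flight_hour_clusters()].
#' @param hours Output of [weighted_hourly_scores()].
#' @param params A [segmentation_params()] object.
#' @return A list of integer vectors (extended, merged clusters).
#' @export
bridge_low_hours <- function(clusters, hours,
                             params = segmentation_params()) {
  if (length(clusters) == 0) return(clusters)
  ext <- lapply(clusters, function(cl) {
    s <- .extend_edge(min(cl), -1L, hours, params)
    e <- .extend_edge(max(cl), +1L, hours, params)
    c(s, e)
  })
  # merge overlapping or adjacent extended intervals into one flight
  ext <- ext[order(vapply(ext, `[`, numeric(1), 1))]
  merged <- list(ext[[1]])
  for (iv in ext[-1]) {
    last <- merged[[length(merged)]]
    if (iv[1] <= last[2] + 1) {
      merged[[length(merged)]] <- c(last[1], max(last[2], iv[2]))
    } else {
      merged <- c(merged, list(iv))
    }
  }
  lapply(merged, function(iv) iv[1]:iv[2])
}

#' Refine a flight-hour cluster to a 5-min-resolution flight bout
#'
#' The bout boundaries are defined around the cluster of high-activity
#' hours: the bout starts at the first record scoring at least
#' `record_flight_score` within the cluster span and ends after the last
#' such record, where the search extends beyond the cluster's hour
#' boundaries (a flight often starts or ends partway through a clock hour
#' whose weighted score stays below the hour threshold) through contiguous
#' non-zero records - a flight only ends where zero scores, or missing
#' records treated as zeros, appear. Records below `record_flight_score`
#' and absent records inside the bout are treated as zeros and excluded
#' from the flight duration (they are assumed not to be landings), so
#' `duration_h` can be shorter than the start-to-end span.
#'
#' @param cluster Integer vector of row indices into `hours`.
#' @param records The 5-min record data.frame.
#' @param hours Output of [weighted_hourly_scores()].
#' @param params A [segmentation_params()] object.
#' @return One-row data.frame (`start`, `end`, `duration_h`, `n_low_omitted`,
#'   `n_missing_as_zero`), or NULL when the cluster holds no record at or
#'   above `record_flight_score` (anomaly: discarded with a message).
#' @export
refine_bout <- function(cluster, records, hours,
                        params = segmentation_params()) {
  span_start <- hours$hour_start[min(cluster)]
  span_end <- hours$hour_start[max(cluster)] + 3600
  ord <- order(records$timestamp_utc)
  tnum <- as.numeric(records$timestamp_utc)[ord]
  score <- records$score[ord]
  high_rec <- score >= params$record_flight_score
  in_span <- tnum >= as.numeric(span_start) & tnum < as.numeric(span_end)
  if (!any(in_span & high_rec)) {
    message("cluster at ", format(span_start), " has no record >= ",
            params$record_flight_score, "; discarded")
    return(NULL)
  }
  i0 <- which(in_span & high_rec)[1]
  i1 <- max(which(in_span & high_rec))
  # extend beyond the hour boundaries: a flight only ends where zero scores
  # (or missing records, treated as zeros) appear, so keep scanning through
  # contiguous non-zero records and move the boundary to the furthest
  # high-score record reached
  # missing records do not end a flight (they are excluded from duration
  # instead), but a gap of an hour or more counts as landed
  n <- length(tnum)
  j <- i0
  while (j > 1 && tnum[j] - tnum[j - 1] <= 12 * 300 && score[j - 1] > 0) {
    j <- j - 1
    if (high_rec[j]) i0 <- j
  }
  j <- i1
  while (j < n && tnum[j + 1] - tnum[j] <= 12 * 300 && score[j + 1] > 0) {
    j <- j + 1
    if (high_rec[j]) i1 <- j
  }
  start <- as.POSIXct(tnum[i0], origin = "1970-01-01", tz = "UTC")
  end <- as.POSIXct(tnum[i1] + 300, origin = "1970-01-01", tz = "UTC")
  inside <- i0:i1
  n_high <- sum(high_rec[inside])
  n_low <- sum(!high_rec[inside])
  n_slots <- (tnum[i1] + 300 - tnum[i0]) / 300
  n_missing <- as.integer(n_slots - length(inside))
  data.frame(start = start, end = end, duration_h = n_high * 5 / 60,
             n_low_omitted = as.integer(n_low),
             n_missing_as_zero = n_missing)
}

# is the midpoint of [start, end] inside any migration season window?
.in_season <- function(start, end, windows) {
  mid <- start + as.numeric(end - start, units = "secs") / 2
  md <- format(mid, "%m-%d")
  any(vapply(windows, function(w) {
    if (w[1] <= w[2]) md >= w[1] && md <= w[2] else md >= w[1] || md <= w[2]
  }, logical(1)))
}

#' Segment an activity stream into flight bouts and stopovers
#'
#' Full classification: weighted hourly scores, candidate-flight-hour
#' clusters, bridging of sub-threshold hours, and 5-min refinement of each
#' bout. Every inter-flight gap becomes a stopover; gaps whose midpoint falls
#' outside the migration season windows, and the periods before the first
#' and after the last flight, are labelled residency.
#'
#' @param records data.frame with `timestamp_utc`, `score` (from an MDL
#'   activity log or [simulate_activity()]).
#' @param params A [segmentation_params()] object.
#' @param windows Migration season windows (default [season_windows]).
#' @return An object of class `mdl_segmentation`: list with `flights`
#'   (data.frame: start, end, duration_h, n_low_omitted, n_missing_as_zero),
#'   `stopovers` (data.frame: start, end, duration_d, role), `hours`, and
#'   `params`.
#' @export
segment_activity <- function(records, params = segmentation_params(),
                             windows = season_windows) {
  if (nrow(records) == 0) {
    empty_f <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          duration_h = numeric(), n_low_omitted = integer(),
                          n_missing_as_zero = integer())
    empty_s <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          duration_d = numeric(), role = character())
    return(structure(list(flights = empty_f, stopovers = empty_s,
                          hours = NULL, params = params),
                     class = "mdl_segmentation"))
  }
  hours <- weighted_hourly_scores(records, params)
  clusters <- find_flight_hour_clusters(hours, params)
  clusters <- bridge_low_hours(clusters, hours, params)
  bouts <- lapply(clusters, refine_bout, records = records, hours = hours,
                  params = params)
  flights <- do.call(rbind, bouts)
  if (is.null(flights)) {
    flights <- data.frame(start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          duration_h = numeric(), n_low_omitted = integer(),
                          n_missing_as_zero = integer())
  } else {
    flights <- flights[order(flights$start), ]
    rownames(flights) <- NULL
  }
  t0 <- min(records$timestamp_utc)
  t1 <- max(records$timestamp_utc) + 300
  gaps <- list()
  if (nrow(flights) == 0) {
    gaps <- list(list(start = t0, end = t1, between = FALSE))
  } else {
    if (t0 < flights$start[1]) {
      gaps <- c(gaps, list(list(start = t0, end = flights$start[1],
                                between = FALSE)))
    }
    if (nrow(flights) > 1) {
      for (i in seq_len(nrow(flights) - 1)) {
        gaps <- c(gaps, list(list(start = flights$end[i],
                                  end = flights$start[i + 1],
                                  between = TRUE)))
      }
    }
    if (flights$end[nrow(flights)] < t1) {
      gaps <- c(gaps, list(list(start = flights$end[nrow(flights)], end = t1,
                                between = FALSE)))
    }
  }
  stopovers <- do.call(rbind, lapply(gaps, function(g) {
    role <- if (g$between && .in_season(g$start, g$end, windows)) {
      "stopover"
    } else {
      "residency"
    }
    data.frame(start = g$start, end = g$end,
               duration_d = as.numeric(g$end - g$start, units = "days"),
               role = role)
  }))
  structure(list(flights = flights, stopovers = stopovers, hours = hours,
                 params = params),
            class = "mdl_segmentation")
}

#' @export
print.mdl_segmentation <- function(x, ...) {
  ns <- sum(x$stopovers$role == "stopover")
  cat(sprintf("MDL activity segmentation: %d flight bout(s), %d stopover(s)\n",
              nrow(x$flights), ns))
  if (nrow(x$flights) > 0) {
    cat(sprintf("  total flight time %.2f h, longest flight %.2f h\n",
                sum(x$flights$duration_h), max(x$flights$duration_h)))
  }
  invisible(x)
}

#' @export
summary.mdl_segmentation <- function(object, ...) {
  summarize_track(object)
}

#' Actogram-style plot of a segmentation
#'
#' Weighted hourly scores over time with detected flight bouts shaded.
#'
#' @param x An `mdl_segmentation`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mdl_segmentation <- function(x, ...) {
  if (is.null(x$hours)) {
    warning("empty segmentation; nothing to plot")
    return(invisible(x))
  }
  graphics::plot(x$hours$hour_start, x$hours$weighted_score, type = "h",
                 xlab = "time (UTC)", ylab = "weighted hourly score",
                 ylim = c(0, 60), col = "grey40", ...)
  graphics::abline(h = x$params$high_hour_threshold, lty = 2)
  if (nrow(x$flights) > 0) {
    graphics::rect(x$flights$start, 0, x$flights$end, 60,
                   col = grDevices::adjustcolor("tomato", 0.25), border = NA)
  }
  invisible(x)
}

#' Per-track summary of flights and stopovers
#'
#' @param x An `mdl_segmentation`, or a flight data.frame (then supply
#'   `stopovers`).
#' @param stopovers Stopover data.frame when `x` is a flight table.
#' @return One-row data.frame: `n_flights`, `total_flight_h`,
#'   `median_flight_h`, `longest_flight_h`, `n_stopovers`,
#'   `total_stopover_d`, `median_stopover_d`. Medians are NA when there are
#'   no bouts.
#' @export
summarize_track <- function(x, stopovers = NULL) {
  if (inherits(x, "mdl_segmentation")) {
    flights <- x$flights
    stopovers <- x$stopovers
  } else {
    flights <- x
  }
  st <- stopovers[stopovers$role == "stopover", , drop = FALSE]
  data.frame(
    n_flights = nrow(flights),
    total_flight_h = if (nrow(flights)) sum(flights$duration_h) else 0,
    median_flight_h = if (nrow(flights)) {
      stats::median(flights$duration_h)
    } else {
      NA_real_
    },
    longest_flight_h = if (nrow(flights)) max(flights$duration_h) else
      NA_real_,
    n_stopovers = nrow(st),
    total_stopover_d = if (nrow(st)) sum(st$duration_d) else 0,
    median_stopover_d = if (nrow(st)) stats::median(st$duration_d) else
      NA_real_)
}
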