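start0 <- as.POSIXct("2019-08-01 00:00:00", tz = "UTC")

test_that("weighted hourly scores span 0 to 60 and treat gaps as zeros", {
  h <- weighted_hourly_scores(hour_records(list(rep(5L, 12))))
  expect_equal(h$weighted_score, 60)
  expect_equal(h$zero_count, 0)
  h <- weighted_hourly_scores(hour_records(list(rep(0L, 12))))
  expect_equal(h$weighted_score, 0)
  expect_equal(h$zero_count, 12)
  # 6 records of score 5, 6 absent: missing records contribute 0
  h <- weighted_hourly_scores(hour_records(list(c(rep(5L, 6), rep(NA, 6)))))
  expect_equal(h$weighted_score, 30)
  expect_equal(h$n_records, 6)
  expect_equal(h$zero_count, 6)
  # the scaled alternative extrapolates the incomplete hour instead
  h2 <- weighted_hourly_scores(hour_records(list(c(rep(5L, 6), rep(NA, 6)))),
                               segmentation_params(weighting = "scaled"))
  expect_equal(h2$weighted_score, 60)
})

test_that("malformed record streams are rejected", {
  r <- hour_records(list(rep(5L, 12)))
  expect_error(weighted_hourly_scores(rbind(r, r[1, ])), "duplicate")
  bad <- r
  bad$timestamp_utc[1] <- bad$timestamp_utc[1] + 17
  expect_error(weighted_hourly_scores(bad), "5-min grid")
  bad2 <- r
  bad2$score[1] <- 7L
  expect_error(weighted_hourly_scores(bad2), "0..5")
})

test_that("flight-hour clusters are maximal runs of high hours", {
  rec <- hour_records(list(rep(1L, 12), rep(5L, 12), rep(5L, 12),
                           rep(1L, 12)))
  h <- weighted_hourly_scores(rec)
  cl <- find_flight_hour_clusters(h)
  expect_length(cl, 1)
  expect_equal(cl[[1]], 2:3)
  # all hours below threshold: none
  low <- weighted_hourly_scores(hour_records(list(rep(2L, 12), rep(1L, 12))))
  expect_length(find_flight_hour_clusters(low), 0)
})

test_that("sub-threshold hours without zero scores stay in flight", {
  # hour 3 averages only 2 per record (weighted 24) but has no zeros
  rec <- hour_records(list(rep(0L, 12), rep(5L, 12), rep(2L, 12),
                           rep(0L, 12)))
  h <- weighted_hourly_scores(rec)
  cl <- bridge_low_hours(find_flight_hour_clusters(h), h)
  expect_equal(cl[[1]], 2:3)
})

test_that("an hour of zeros plus the next hour's zeros ends the flight", {
  # adjacent hour has 6 zeros, following hour 6 zeros: sum 12 -> landed
  rec <- hour_records(list(rep(5L, 12), c(rep(4L, 6), rep(0L, 6)),
                           c(rep(2L, 6), rep(0L, 6)), rep(0L, 12)))
  h <- weighted_hourly_scores(rec)
  cl <- bridge_low_hours(find_flight_hour_clusters(h), h)
  expect_equal(cl[[1]], 1L)
  # with only 3 + 2 zeros the bird is still flying and the clusters merge
  rec <- hour_records(list(rep(5L, 12), c(rep(4L, 9), rep(0L, 3)),
                           c(rep(4L, 10), rep(0L, 2)), rep(5L, 12)))
  h <- weighted_hourly_scores(rec)
  cl <- bridge_low_hours(find_flight_hour_clusters(h), h)
  expect_length(cl, 1)
  expect_equal(cl[[1]], 1:4)
})

test_that("bout refinement has 5-min resolution and omits low scores", {
  # exact block of 100 records scoring 4, flanked by zeros
  rec <- rbind(block_records(0L, 2, start0),
               block_records(4L, 100, start0 + 2 * 300),
               block_records(0L, 34, start0 + 102 * 300))
  seg <- segment_activity(rec)
  expect_equal(nrow(seg$flights), 1)
  expect_equal(seg$flights$start, start0 + 2 * 300)
  expect_equal(seg$flights$duration_h, 100 * 5 / 60)
  # 104 contiguous records >= 3: the autumn-median-scale bout
  rec <- rbind(block_records(5L, 104, start0),
               block_records(0L, 30, start0 + 104 * 300))
  seg <- segment_activity(rec)
  expect_equal(seg$flights$duration_h, 104 * 5 / 60)  # 8.667 h
  # two interior low-score records: span unchanged, duration 10 min less
  sc <- rep(4L, 100)
  sc[c(40, 60)] <- 1L
  rec <- rbind(block_records(0L, 2, start0),
               data.frame(timestamp_utc = start0 + 2 * 300 +
                            300 * (seq_len(100) - 1),
                          score = sc, n_subsamples = 5L),
               block_records(0L, 34, start0 + 102 * 300))
  seg <- segment_activity(rec)
  expect_equal(as.numeric(seg$flights$end - seg$flights$start,
                          units = "mins"), 100 * 5)
  expect_equal(seg$flights$duration_h, 98 * 5 / 60)
  expect_equal(seg$flights$n_low_omitted, 2L)
})

test_that("a record scoring exactly 3 counts as flight", {
  rec <- rbind(block_records(0L, 2, start0),
               block_records(3L, 96, start0 + 2 * 300),
               block_records(0L, 22, start0 + 98 * 300))
  seg <- segment_activity(rec)
  expect_equal(seg$flights$duration_h, 96 * 5 / 60)
})

test_that("missing in-flight records are excluded from flight duration", {
  sc <- c(rep(NA, 0), rep(5L, 50), rep(NA, 4), rep(5L, 50))
  rec <- rbind(block_records(0L, 12, start0),
               data.frame(timestamp_utc = start0 + 12 * 300 +
                            300 * (seq_along(sc) - 1),
                          score = sc, n_subsamples = 5L),
               block_records(0L, 24, start0 + (12 + 104) * 300))
  rec <- rec[!is.na(rec$score), ]
  seg <- segment_activity(rec)
  expect_equal(nrow(seg$flights), 1)
  expect_equal(seg$flights$duration_h, 100 * 5 / 60)
  expect_equal(seg$flights$n_missing_as_zero, 4L)
  # elapsed span exceeds duration exactly by the missing slots
  span_h <- as.numeric(seg$flights$end - seg$flights$start, units = "hours")
  expect_equal(span_h, seg$flights$duration_h + 4 * 5 / 60)
})

test_that("segmentation recovers planted bouts exactly on noiseless data", {
  for (seed in c(1, 11, 21)) {
    it <- make_itinerary(n_stopovers = 4, seed = seed)
    act <- simulate_activity(it)
    seg <- segment_activity(act)
    tr <- attr(act, "truth")
    expect_equal(nrow(seg$flights), nrow(tr))
    expect_equal(as.numeric(seg$flights$start), as.numeric(tr$start))
    expect_equal(as.numeric(seg$flights$end), as.numeric(tr$end))
    expect_equal(seg$flights$duration_h, tr$duration_h)
    # flights and stopovers tile the record span without overlap
    segs <- rbind(
      data.frame(s = as.numeric(seg$flights$start),
                 e = as.numeric(seg$flights$end)),
      data.frame(s = as.numeric(seg$stopovers$start),
                 e = as.numeric(seg$stopovers$end)))
    segs <- segs[order(segs$s), ]
    expect_equal(segs$s[-1], segs$e[-nrow(segs)])
    expect_equal(segs$s[1], as.numeric(min(act$timestamp_utc)))
    expect_equal(segs$e[nrow(segs)],
                 as.numeric(max(act$timestamp_utc) + 300))
    # inter-flight gaps in season are stopovers, margins are residency
    expect_equal(sum(seg$stopovers$role == "stopover"), nrow(tr) - 1)
  }
})

test_that("the longest recorded flight scale is recovered exactly", {
  # a planted 57.2 h non-stop flight (the longest autumn flight magnitude)
  n <- round(57.2 * 12)
  rec <- rbind(block_records(0L, 24, start0),
               block_records(5L, n, start0 + 24 * 300),
               block_records(0L, 24, start0 + (24 + n) * 300))
  seg <- segment_activity(rec)
  expect_equal(nrow(seg$flights), 1)
  expect_equal(seg$flights$duration_h, n / 12, tolerance = 1e-9)
  expect_equal(seg$flights$duration_h, 57.2, tolerance = 0.01)
})

test_that("raising the hour threshold never adds clusters", {
  set.seed(99)
  sc <- lapply(1:72, function(i) pmin(5L, pmax(0L, as.integer(
    rpois(12, lambda = sample(c(0.3, 4), 1))))))
  h <- weighted_hourly_scores(hour_records(sc))
  n_prev <- Inf
  for (thr in c(20, 30, 40, 50, 60)) {
    n <- length(find_flight_hour_clusters(
      h, segmentation_params(high_hour_threshold = thr)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("track summaries aggregate bout tables", {
  it <- make_itinerary(n_stopovers = 2, seed = 4)
  act <- simulate_activity(it)
  seg <- segment_activity(act)
  s <- summarize_track(seg)
  expect_equal(s$n_flights, 3)
  expect_equal(s$total_flight_h, sum(attr(act, "truth")$duration_h))
  expect_equal(s$median_flight_h, median(attr(act, "truth")$duration_h))
  # empty input: empty segmentation, missing medians
  seg0 <- segment_activity(act[0, ])
  expect_equal(nrow(seg0$flights), 0)
  s0 <- summarize_track(seg0)
  expect_equal(s0$n_flights, 0)
  expect_true(is.na(s0$median_flight_h))
})

test_that("total flight time grows with migration distance in a cohort", {
  dests <- list(c(50, 0), c(45, -3), c(40, -6), c(36, -7))
  res <- t(vapply(seq_along(dests), function(i) {
    it <- make_itinerary(destination = dests[[i]], n_stopovers = 2,
                         seed = 30 + i)
    seg <- segment_activity(simulate_activity(it))
    c(d = haversine(ottenby[1], ottenby[2], dests[[i]][1], dests[[i]][2]),
      fh = summarize_track(seg)$total_flight_h)
  }, numeric(2)))
  fit <- lm(fh ~ d, data = as.data.frame(res))
  expect_gt(coef(fit)[2], 0)
})
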