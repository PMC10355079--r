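winter <- c(as.POSIXct("2019-11-15", tz = "UTC"),
            as.POSIXct("2019-12-15", tz = "UTC"))

test_that("twilight detection recovers threshold-crossing times", {
  lt <- simulate_light(c(40, -5), sun_angle = -6, start = winter[1],
                       end = winter[2])
  tw <- detect_twilights(lt, 2)
  expect_true(all(tw$kind %in% c("rise", "set")))
  # crossing times sit within one sample interval of the true elevation
  # crossing (elevation exactly equal to the sun angle)
  elev <- solar_elevation(tw$time, 40, -5)
  expect_lt(max(abs(elev - (-6))), 0.2)
  # rises and sets alternate
  expect_true(all(tw$kind[-1] != tw$kind[-nrow(tw)]))
})

test_that("constant darkness yields no events and flags the days", {
  dark <- data.frame(
    timestamp_utc = seq(winter[1], winter[1] + 3 * 86400, by = 300),
    lux = 0)
  tw <- detect_twilights(dark, 2)
  expect_equal(nrow(tw), 0)
  expect_gte(length(attr(tw, "no_crossing_days")), 3)
})

test_that("a mid-night light spike is removed by twilight editing", {
  lt <- simulate_light(c(40, -5), sun_angle = -6, start = winter[1],
                       end = winter[1] + 10 * 86400)
  # artificial light at 00:30 on night 5
  spike_at <- winter[1] + 4 * 86400 + 30 * 60
  lt$lux[abs(as.numeric(lt$timestamp_utc - spike_at, units = "secs")) <
           600] <- 50
  tw <- detect_twilights(lt, 2)
  n_spurious <- sum(as.numeric(format(tw$time, "%H")) %in% c(0, 1))
  expect_gt(n_spurious, 0)
  ed <- edit_twilights(tw)
  expect_equal(sum(as.numeric(format(ed$time, "%H")) %in% c(0, 1)), 0)
  # a clean series passes through unchanged (except window-edge events
  # lacking neighbours)
  clean <- detect_twilights(simulate_light(c(40, -5), sun_angle = -6,
                                           start = winter[1],
                                           end = winter[1] + 10 * 86400), 2)
  ed2 <- edit_twilights(clean)
  expect_false(any(ed2$edited))
})

test_that("a shading-shifted sunset is restored from neighbouring days", {
  lt <- simulate_light(c(40, -5), sun_angle = -6, start = winter[1],
                       end = winter[1] + 9 * 86400)
  tw <- detect_twilights(lt, 2)
  sets <- which(tw$kind == "set")
  mid <- sets[5]
  true_time <- tw$time[mid]
  tw$time[mid] <- tw$time[mid] - 3 * 3600  # 3 h early by shading
  ed <- edit_twilights(tw)
  i <- which(ed$kind == "set" & as.Date(ed$time) == as.Date(true_time))
  expect_length(i, 1)
  expect_true(ed$edited[i])
  expect_lt(abs(as.numeric(ed$time[i] - true_time, units = "mins")), 10)
  # an event with no neighbours in the window is dropped
  lone <- tw[c(1, 2), ]
  lone$time[2] <- lone$time[2] + 30 * 86400
  expect_equal(nrow(edit_twilights(lone)), 0)
})

test_that("equinox day length carries no latitude information", {
  eq <- as.POSIXct("2020-03-20 06:00:00", tz = "UTC")
  p <- position_from_twilight_pair(eq, eq + 12 * 3600, sun_angle = 0)
  expect_false(p$lat_defined)
  expect_true(is.finite(p$lon))
  expect_error(position_from_twilight_pair(eq, eq - 3600), "0 < set - rise")
})

test_that("noiseless round-trip recovers the true position", {
  lt <- simulate_light(c(40, -5), sun_angle = -6, start = winter[1],
                       end = winter[2])
  pos <- twilight_positions(detect_twilights(lt, 2), sun_angle = -6)
  expect_gt(nrow(pos), 25)
  expect_true(all(pos$lat_defined))
  expect_lt(max(abs(pos$lon - (-5))), 0.3)
  expect_lt(max(abs(pos$lat - 40)), 0.7)
})

test_that("longitude recovery error does not depend on latitude", {
  errs <- vapply(c(0, 20, 40, 60), function(lat) {
    lt <- simulate_light(c(lat, 12), sun_angle = -6, start = winter[1],
                         end = winter[1] + 6 * 86400)
    pos <- twilight_positions(detect_twilights(lt, 2), sun_angle = -6)
    max(abs(pos$lon - 12))
  }, numeric(1))
  expect_true(all(errs < 0.3))
})

test_that("latitude error grows toward the equinox", {
  # fixed site, wrong-free geometry: absolute latitude error by declination
  lt <- simulate_light(c(40, -5), sun_angle = -6,
                       start = as.POSIXct("2019-09-26", tz = "UTC"),
                       end = as.POSIXct("2019-11-15", tz = "UTC"))
  pos <- twilight_positions(detect_twilights(lt, 2), sun_angle = -6)
  pos <- pos[pos$lat_defined, ]
  err <- abs(pos$lat - 40)
  decl <- abs(vapply(pos$date, function(d) {
    solar_position(as.POSIXct(paste(d, "12:00:00"), tz = "UTC"))$declination
  }, numeric(1)))
  # dividing at |declination| = 5 degrees: near-equinox errors dominate
  expect_gt(mean(err[decl < 5]), mean(err[decl > 10]))
  expect_lt(max(err[decl > 5]), 0.7)
})

test_that("Hill-Ekstrom calibration recovers the true sun angle", {
  lt <- simulate_light(c(40, -5), sun_angle = -4.5,
                       start = as.POSIXct("2019-09-01", tz = "UTC"),
                       end = as.POSIXct("2019-10-10", tz = "UTC"))
  he <- hill_ekstrom_calibrate(detect_twilights(lt, 2))
  expect_false(he$failed)
  expect_lt(abs(he$sun_angle - (-4.5)), 0.2 + 1e-9)
  # the objective at the true angle beats the true angle +/- 1 degree
  oc <- he$objective_curve
  obj_at <- function(a) oc$objective[which.min(abs(oc$angle - a))]
  expect_lte(obj_at(-4.5), obj_at(-3.5))
  expect_lte(obj_at(-4.5), obj_at(-5.5))
})

test_that("calibration on pure noise fails loudly", {
  set.seed(8)
  noise <- data.frame(
    timestamp_utc = seq(winter[1], winter[1] + 30 * 86400, by = 300),
    lux = runif(8641, 0, 4))
  tw <- detect_twilights(noise, 2)
  ed <- edit_twilights(tw)
  expect_warning(he <- hill_ekstrom_calibrate(ed), "failed")
  expect_true(he$failed)
  expect_true(is.na(he$sun_angle))
})

test_that("stationary periods are found by longitude change-points", {
  d0 <- as.Date("2019-11-01")
  # constant site: one period spanning everything
  p1 <- data.frame(date = d0 + 0:19, lat = 40 + rnorm(20, 0, 0.05),
                   lon = -5 + rnorm(20, 0, 0.05), lat_defined = TRUE)
  set.seed(2)
  sp1 <- stationary_periods(p1)
  expect_equal(nrow(sp1), 1)
  expect_equal(sp1$n_days, 20)
  # two 20-day sites 5 degrees of longitude apart
  p2 <- rbind(p1, data.frame(date = d0 + 20:39,
                             lat = 38 + rnorm(20, 0, 0.05),
                             lon = 0 + rnorm(20, 0, 0.05),
                             lat_defined = TRUE))
  sp2 <- stationary_periods(p2)
  expect_equal(nrow(sp2), 2)
  expect_equal(sp2$mean_lon, c(-5, 0), tolerance = 0.05)
  expect_equal(sp2$mean_lat, c(40, 38), tolerance = 0.05)
  expect_equal(sp2$n_days, c(20, 20))
  # a 2-day visit between long stays is not resolved as its own period
  p3 <- rbind(p1,
              data.frame(date = d0 + 20:21, lat = 39, lon = -4.6,
                         lat_defined = TRUE),
              data.frame(date = d0 + 22:41, lat = 40 + rnorm(20, 0, 0.05),
                         lon = -5 + rnorm(20, 0, 0.05), lat_defined = TRUE))
  sp3 <- stationary_periods(p3)
  expect_false(any(sp3$n_days < 3))
  expect_false(any(abs(sp3$mean_lon - (-4.6)) < 0.2))
})

test_that("periods with undefined latitudes keep longitude statistics", {
  d0 <- as.Date("2020-03-10")
  p <- data.frame(date = d0 + 0:9, lat = NA_real_, lon = 2 + rnorm(10, 0, 0.1),
                  lat_defined = FALSE)
  sp <- stationary_periods(p)
  expect_equal(nrow(sp), 1)
  expect_true(is.na(sp$mean_lat))
  expect_equal(sp$mean_lon, 2, tolerance = 0.1)
})
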