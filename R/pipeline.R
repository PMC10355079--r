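#' Default pipeline configuration
#'
#' Configuration for [run_pipeline()]: a small synthetic cohort run through
#' simulation, segmentation, geolocation, route metrics and the optimality
#' models.
#'
#' @param seed Master integer seed.
#' @param n_birds Number of synthetic birds.
#' @param destinations List of `c(lat, lon)` wintering sites (recycled over
#'   birds).
#' @param n_stopovers Stopovers per bird (recycled).
#' @param noise An [mdl_noise()] specification.
#' @param sun_angle True/assumed sun elevation angle for light simulation
#'   and geolocation, degrees.
#' @param threshold Lux threshold.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_birds = 3,
                            destinations = list(c(46.0, -2.0), c(40.0, -6.0),
                                                c(36.0, -6.5)),
                            n_stopovers = c(2, 3, 4),
                            noise = mdl_noise(p_active_rest = 0.05,
                                              p_inactive_flight = 0.02,
                                              p_missing_record = 0.01),
                            sun_angle = -6, threshold = 2) {
  structure(list(seed = as.integer(seed), n_birds = n_birds,
                 destinations = destinations, n_stopovers = n_stopovers,
                 noise = noise, sun_angle = sun_angle, threshold = threshold),
            class = "pipeline_config")
}

#' Run the full synthetic-data analysis pipeline
#'
#' simulate -> segment -> geolocate -> route metrics -> optimality models,
#' writing one CSV per stage plus a JSON run manifest to `out_dir`. Outputs
#' are deterministic for a fixed seed; numeric columns carry their unit in
#' the name (`_h`, `_d`, `_km`, `_deg`).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the per-stage tables (`bouts`,
#'   `track_summaries`, `winter_positions`, `routes`, `energy_grid`,
#'   `time_grid`) and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bouts <- list()
  summaries <- list()
  winters <- list()
  routes <- list()
  for (b in seq_len(config$n_birds)) {
    seed_b <- config$seed * 1000L + b
    dest <- config$destinations[[(b - 1) %% length(config$destinations) + 1]]
    nst <- config$n_stopovers[[(b - 1) %% length(config$n_stopovers) + 1]]
    it <- make_itinerary(destination = dest, n_stopovers = nst, seed = seed_b)
    act <- simulate_activity(it, noise = config$noise)
    seg <- segment_activity(act)
    if (nrow(seg$flights) > 0) {
      bouts[[b]] <- data.frame(track_id = b, kind = "flight",
                               start_utc = seg$flights$start,
                               end_utc = seg$flights$end,
                               duration_h = seg$flights$duration_h,
                               n_low_omitted = seg$flights$n_low_omitted)
    }
    s <- summarize_track(seg)
    s <- cbind(track_id = b, s)
    summaries[[b]] <- s
    # winter geolocation from the December + February light windows
    lt <- simulate_light(it, sun_angle = config$sun_angle,
                         threshold = config$threshold,
                         p_shading = config$noise$p_shading,
                         start = min(it$flights$start) - 2 * 86400,
                         end = max(it$flights$end) + 150 * 86400,
                         windows = mdl_light_windows[c("december",
                                                       "february")],
                         seed = seed_b)
    tw <- edit_twilights(detect_twilights(lt, config$threshold))
    pos <- twilight_positions(tw, sun_angle = config$sun_angle)
    if (nrow(pos) > 0) {
      sp <- stationary_periods(pos)
      if (nrow(sp) > 0) {
        main <- sp[which.max(sp$n_days), ]
        winters[[b]] <- data.frame(track_id = b,
                                   mean_lat_deg = main$mean_lat,
                                   mean_lon_deg = main$mean_lon,
                                   sd_lat_deg = main$sd_lat,
                                   sd_lon_deg = main$sd_lon,
                                   n_days = main$n_days)
        d_km <- haversine(ottenby[1], ottenby[2],
                          main$mean_lat, main$mean_lon)
        di <- detour_index(it$sites[, c("lat", "lon")])
        routes[[b]] <- data.frame(track_id = b,
                                  migration_distance_km = d_km,
                                  route_distance_km = di$route_distance_km,
                                  detour_index = di$detour_index)
      }
    }
  }
  energy <- sweep_energy()
  time <- sweep_time()
  out <- list(bouts = do.call(rbind, bouts),
              track_summaries = do.call(rbind, summaries),
              winter_positions = do.call(rbind, winters),
              routes = do.call(rbind, routes),
              energy_grid = as.data.frame(energy),
              time_grid = as.data.frame(time))
  files <- c(bouts = "bouts.csv", track_summaries = "track_summaries.csv",
             winter_positions = "winter_positions.csv", routes = "routes.csv",
             energy_grid = "energy_grid.csv", time_grid = "time_grid.csv")
  for (nm in names(files)) {
    if (!is.null(out[[nm]])) {
      utils::write.csv(out[[nm]], file.path(out_dir, files[[nm]]),
                       row.names = FALSE)
    }
  }
  manifest <- list(
    package = "mdltools",
    version = as.character(utils::packageVersion("mdltools")),
    seed = config$seed, n_birds = config$n_birds,
    sun_angle_deg = config$sun_angle, threshold_lux = config$threshold,
    noise = unclass(config$noise),
    files = unname(files[vapply(names(files),
                                function(nm) !is.null(out[[nm]]),
                                logical(1))]))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
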