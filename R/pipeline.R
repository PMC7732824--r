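## Pipeline orchestration: a single serialisable configuration object and a
## run_pipeline() driver binding simulate -> segment -> metrics -> annotate
## -> compare, with a manifest of seeds, versions and output hashes.

.default_config <- function() {
  list(
    light_threshold = 1,          # on log-transformed light
    stopover_radius_km = 150,
    stopover_min_days = 3,
    speed_min_kmh = 20,
    speed_max_gap_h = 24,
    duty_on_h = 10, duty_off_h = 48,
    lapse_c_per_km = 6.5,
    elevation_bin_deg = 0.1,
    breeding_lat = 30,
    crest_elevation = 4000,
    n_resamples = 9999,
    speed_prior_shape = 2.2, speed_prior_rate = 0.08,
    flight_speed_kmh = 55,
    flight_altitude = 4000,
    shading_shape = 2, shading_rate = 0.5,
    sun_angle = -3.5,
    start_date = "2019-04-20",
    pass_lon = 92, pass_floor = 4720,
    birds = list(
      list(id = "hima1", route = "himalayan",
           out = list(lat = c(1.45, 17, 28.5, 33), lon = c(103.73, 96.5, 92, 91)),
           stop_days = c(6, 8, 0, 70)),
      list(id = "east1", route = "eastern",
           out = list(lat = c(1.45, 13, 25, 36), lon = c(103.73, 100, 101, 99)),
           stop_days = c(6, 9, 4, 70))))
}

#' Pipeline configuration
#'
#' All tunables of the analysis chain with defaults at the study's stated
#' values (150 km / 3-day stopover rule, 20 km/h speed filter, 10 h on /
#' 48 h off duty cycle, 6.5 degC/km lapse rate, 0.1 degree elevation bins,
#' 9999 permutation resamples, gamma(2.2, 0.08) speed prior, light threshold
#' 1). Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return List of class `flytrack_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- .default_config()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = c("flytrack_config", "list"))
}

#' @rdname pipeline_config
#' @param path YAML file of overrides.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Simulates the configured birds' round-trip migrations, degrades them to
#' duty-cycled Argos fixes, segments stopovers and seasonal phases, computes
#' migration summaries and ground speeds, annotates wind support (three
#' pressure levels and their maximum) and minimum-elevation profiles over
#' the synthetic ridge DEM, detects barrier crossings, and compares routes
#' with permutation tests and wind regressions. All outputs are written as
#' CSV/JSON under `out_dir` together with a manifest (package version, seed,
#' configuration hash, and an MD5 per output file).
#'
#' @param config A [pipeline_config()].
#' @param seed Integer master seed.
#' @param out_dir Output directory (created; existing files are
#'   overwritten only on a clean rerun of the same stage).
#' @param quiet Suppress stage timings on stderr.
#' @return Invisibly, a list with the in-memory artifacts (`tracks`,
#'   `summaries`, `legs`, `profiles`, `crossings`, `tests`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = tempfile("flytrack_run_"), quiet = FALSE) {
  stopifnot(inherits(config, "flytrack_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()

  dem <- make_dem(passes = data.frame(lon = config$pass_lon,
                                      floor = config$pass_floor, width = 0.3))
  times <- seq(as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC"),
               by = "30 days", length.out = 8)
  wf <- make_wind_field(times = times,
                        perturb_sd = 8, seed = seed + 100L)

  tracks <- list(); summaries <- list(); legs <- list()
  profiles <- list(); crossings <- list()
  for (bi in seq_along(config$birds)) {
    bird <- config$birds[[bi]]
    wp_out <- data.frame(lat = bird$out$lat, lon = bird$out$lon)
    wp <- rbind(wp_out, wp_out[rev(seq_len(nrow(wp_out) - 1)), ])
    stop_days <- c(bird$stop_days, rep(0, nrow(wp_out) - 2), 10)
    plan <- simulation_plan(
      wp, stopover_days = stop_days,
      start_time = as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC"),
      flight_speed_kmh = config$flight_speed_kmh,
      flight_altitude = config$flight_altitude,
      duty_cycle = c(on = config$duty_on_h, off = config$duty_off_h),
      shading_shape = config$shading_shape, shading_rate = config$shading_rate,
      sun_angle = config$sun_angle, seed = seed + bi)
    truth <- simulate_track(plan, bird_id = bird$id)
    argos <- degrade_to_argos(truth, plan)
    say("simulated %s: %d truth / %d argos fixes", bird$id, nrow(truth),
        nrow(argos))
    seg <- detect_stopovers(argos, config$stopover_radius_km,
                            config$stopover_min_days)
    ph <- assign_phases(argos, seg, config$breeding_lat)
    tracks[[bird$id]] <- argos
    if (!ph$partial) {
      phs <- ph$phases
      for (dirn in c("northward", "southward")) {
        row <- phs[phs$phase == dirn, ]
        if (!nrow(row)) next
        sm <- summarise_migration(argos, seg$stopovers, row$start, row$end,
                                  direction = if (dirn == "northward")
                                    "north" else "south")
        sm$bird_id <- bird$id; sm$route <- bird$route
        summaries[[paste(bird$id, dirn)]] <- sm
        sel_t <- argos[argos$time >= row$start & argos$time <= row$end, ]
        if (nrow(sel_t) >= 2) {
          prof <- min_elevation_profile(as_track(sel_t), dem,
                                        config$elevation_bin_deg)
          profiles[[paste(bird$id, dirn)]] <- data.frame(
            bird_id = bird$id, route = bird$route, direction = sm$direction,
            mean_masl = prof$mean_masl)
        }
      }
    }
    sp <- ground_speeds(argos, config$speed_min_kmh, config$speed_max_gap_h)
    sp <- sp[sp$retained, ]
    if (nrow(sp)) {
      ann <- list()
      for (lv in c("surface", "mb850", "mb700", "max"))
        ann[[lv]] <- wind_support(sp, wf, lv)
      ann <- do.call(rbind, ann)
      ann$bird_id <- bird$id; ann$route <- bird$route
      # leg direction for route x direction models
      ann$direction <- ifelse(ann$lat2 >= ann$lat1, "north", "south")
      legs[[bird$id]] <- ann
    }
    bc <- detect_barrier_crossing(argos, dem, config$crest_elevation)
    if (nrow(bc)) crossings[[bird$id]] <- cbind(bird_id = bird$id, bc)
    say("segmented %s: %d stopovers, partial = %s", bird$id,
        nrow(seg$stopovers), ph$partial)
  }
  summaries <- do.call(rbind, summaries)
  legs <- do.call(rbind, legs)
  profiles <- do.call(rbind, profiles)
  crossings <- do.call(rbind, Filter(nrow, crossings))

  tests <- list()
  if (!is.null(summaries) && length(unique(summaries$route)) > 1) {
    for (dirn in unique(summaries$direction)) {
      s <- summaries[summaries$direction == dirn, ]
      if (min(table(s$route)) >= 2) {
        pt <- permutation_test(
          s$migration_distance_km[s$route == "himalayan"],
          s$migration_distance_km[s$route == "eastern"],
          n_resamples = config$n_resamples, seed = seed + 50L)
        tests[[paste0("distance_", dirn)]] <-
          data.frame(comparison = paste0("distance_", dirn),
                     Z = pt$Z, p = pt$p)
      }
    }
  }
  if (!is.null(legs)) {
    for (lv in c("surface", "mb850", "mb700", "max")) {
      l <- legs[legs$level == lv & is.finite(legs$support_kmh), ]
      if (nrow(l) >= 3) {
        fg <- fit_speed_wind(l$speed_kmh, l$support_kmh)
        fa <- fit_speed_wind(l$air_speed_kmh, l$support_kmh)
        tests[[paste0("speed_wind_", lv)]] <- data.frame(
          comparison = paste0("speed_wind_", lv),
          Z = NA_real_, p = fg$p[1],
          ground_slope = fg$estimate[fg$term == "support"],
          air_slope = fa$estimate[fa$term == "support"],
          r_squared = fg$r_squared[1])
      }
    }
  }

  paths <- character()
  wr <- function(obj, name, fun = utils::write.csv) {
    p <- file.path(out_dir, name)
    if (is.null(obj)) return(invisible(NULL))
    fun(obj, p)
    paths[[name]] <<- p
  }
  for (id in names(tracks))
    wr(tracks[[id]], paste0("track_", id, ".csv"), write_track_csv)
  wr(summaries, "migration_summaries.csv",
     function(x, p) utils::write.csv(x, p, row.names = FALSE))
  wr(legs, "wind_legs.csv",
     function(x, p) utils::write.csv(x, p, row.names = FALSE))
  wr(profiles, "elevation_profiles.csv",
     function(x, p) utils::write.csv(x, p, row.names = FALSE))
  wr(crossings, "barrier_crossings.csv",
     function(x, p) utils::write.csv(x, p, row.names = FALSE))
  if (length(tests))
    wr(do.call(rbind, lapply(tests, function(t) {
      t[setdiff(c("comparison", "Z", "p", "ground_slope", "air_slope",
                  "r_squared"), names(t))] <- NA
      t[c("comparison", "Z", "p", "ground_slope", "air_slope", "r_squared")]
    })), "route_tests.csv",
    function(x, p) utils::write.csv(x, p, row.names = FALSE))

  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  manifest <- list(
    package = "flytrack",
    version = tryCatch(as.character(utils::packageVersion("flytrack")),
                       error = function(e) "dev"),
    r_version = as.character(getRversion()),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = as.list(vapply(paths, function(p) unname(tools::md5sum(p)),
                             character(1))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("pipeline finished in %.1f s", as.numeric(difftime(Sys.time(), t_start,
                                                         units = "secs")))
  invisible(list(tracks = tracks, summaries = summaries, legs = legs,
                 profiles = profiles, crossings = crossings, tests = tests,
                 manifest = manifest, out_dir = out_dir))
}
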