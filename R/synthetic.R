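## Synthetic-data generators: ground-truth migrations and their degradation
## into the sensor products the pipeline consumes (Argos fixes, geolocator
## light/temperature/wetness, DEM, wind fields). All generators are seeded.

# position at fraction f along the great circle p1 -> p2 (slerp on the sphere)
.gc_point <- function(lat1, lon1, lat2, lon2, f) {
  to_xyz <- function(lat, lon) {
    la <- lat * .deg2rad; lo <- lon * .deg2rad
    cbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
  }
  a <- to_xyz(lat1, lon1)[1, ]; b <- to_xyz(lat2, lon2)[1, ]
  omega <- acos(min(1, max(-1, sum(a * b))))
  if (omega < 1e-12) stop("identical waypoints in great-circle leg")
  w1 <- sin((1 - f) * omega) / sin(omega)
  w2 <- sin(f * omega) / sin(omega)
  p <- outer(w1, a) + outer(w2, b)
  p <- p / sqrt(rowSums(p^2))
  data.frame(lat = asin(p[, 3]) * .rad2deg, lon = atan2(p[, 2], p[, 1]) * .rad2deg)
}

#' Define a simulation plan
#'
#' The plan fixes every aspect of a simulated migration: the waypoint chain
#' (non-breeding site, stopovers, breeding site, optionally the return),
#' residency durations, flight speed and altitude, the transmitter duty
#' cycle, the twilight shading model, and the seed.
#'
#' @param waypoints data.frame with columns `lat`, `lon` and optionally
#'   `altitude` (masl, default 0): the sites visited in order.
#' @param stopover_days Days of residency at each waypoint, a vector of
#'   length `nrow(waypoints)`; the first and last entries are the residencies
#'   at the terminal sites.
#' @param start_time POSIXct (UTC) start of the simulation at waypoint 1.
#' @param flight_speed_kmh Ground speed on migratory legs (km/h).
#' @param flight_altitude Cruise altitude on legs (masl).
#' @param duty_cycle `c(on, off)` transmitter hours, the tags' 10 h on /
#'   48 h off schedule by default.
#' @param shading_shape,shading_rate Gamma parameters of the twilight shading
#'   delay (minutes): shading darkens, so it delays dawn and advances dusk.
#' @param sun_angle True sun elevation angle (degrees) at which the logged
#'   light crosses the detection threshold.
#' @param jitter_km Within-site position jitter radius (km), well below the
#'   150 km segmentation radius.
#' @param wet_prob Hourly immersion probability while stationary (tidal
#'   foraging); flight hours are always dry.
#' @param seed Integer seed governing all randomness downstream.
#' @return A list of class `flytrack_plan`.
#' @export
simulation_plan <- function(waypoints,
                            stopover_days = rep(0, nrow(waypoints)),
                            start_time = as.POSIXct("2019-01-15 00:00:00", tz = "UTC"),
                            flight_speed_kmh = 55,
                            flight_altitude = 4000,
                            duty_cycle = c(on = 10, off = 48),
                            shading_shape = 2, shading_rate = 0.5,
                            sun_angle = -3.5,
                            jitter_km = 0.3,
                            wet_prob = 0.6,
                            seed = 1L) {
  stopifnot(is.data.frame(waypoints), nrow(waypoints) >= 2,
            all(c("lat", "lon") %in% names(waypoints)))
  if (is.null(waypoints$altitude)) waypoints$altitude <- 0
  stopover_days <- rep_len(stopover_days, nrow(waypoints))
  if (any(stopover_days < 0)) stop("stopover_days must be >= 0")
  if (flight_speed_kmh <= 0) stop("flight_speed_kmh must be > 0")
  if (shading_shape <= 0 || shading_rate <= 0) stop("gamma parameters must be > 0")
  structure(list(waypoints = waypoints, stopover_days = stopover_days,
                 start_time = as.POSIXct(start_time, tz = "UTC"),
                 flight_speed_kmh = flight_speed_kmh,
                 flight_altitude = flight_altitude,
                 duty_cycle = duty_cycle,
                 shading_shape = shading_shape, shading_rate = shading_rate,
                 sun_angle = sun_angle, jitter_km = jitter_km,
                 wet_prob = wet_prob, seed = as.integer(seed)),
            class = "flytrack_plan")
}

#' Simulate a ground-truth track
#'
#' Hourly TRUTH fixes following great-circle legs at the planned ground speed
#' between waypoints, with small jitter during residencies. Phase labels
#' (`siteNN` / `legNN`) and true altitude are carried in the track.
#'
#' @param plan A [simulation_plan()].
#' @param bird_id,species Track metadata.
#' @return A `flytrack_track` of TRUTH fixes at 1-h cadence.
#' @export
simulate_track <- function(plan, bird_id = "sim1", species = "other") {
  stopifnot(inherits(plan, "flytrack_plan"))
  set.seed(plan$seed)
  wp <- plan$waypoints
  n_wp <- nrow(wp)
  segs <- list()   # per segment: hours, fun(hour_in_seg) -> lat/lon/alt/phase
  for (i in seq_len(n_wp)) {
    if (plan$stopover_days[i] > 0) {
      segs[[length(segs) + 1]] <- list(kind = "site", idx = i,
                                       hours = plan$stopover_days[i] * 24)
    }
    if (i < n_wp) {
      d_km <- geosphere::distHaversine(c(wp$lon[i], wp$lat[i]),
                                       c(wp$lon[i + 1], wp$lat[i + 1]), r = 6371)
      if (d_km < 1e-6) stop("consecutive waypoints are identical")
      segs[[length(segs) + 1]] <- list(kind = "leg", idx = i,
                                       hours = d_km / plan$flight_speed_kmh)
    }
  }
  t0 <- 0
  out <- list()
  for (s in segs) {
    hh <- seq(ceiling(t0), floor(t0 + s$hours - 1e-9))
    hh <- hh[hh >= t0]
    if (s$kind == "site") {
      n <- length(hh)
      if (n) {
        # isotropic jitter within jitter_km
        ang <- stats::runif(n, 0, 360)
        rad <- plan$jitter_km * sqrt(stats::runif(n)) * 1000
        p <- geosphere::destPoint(cbind(wp$lon[s$idx], wp$lat[s$idx]), ang, rad,
                                  r = 6371000)
        out[[length(out) + 1]] <- data.frame(
          hour = hh, lat = p[, 2], lon = p[, 1],
          altitude = wp$altitude[s$idx], phase = sprintf("site%02d", s$idx))
      }
    } else {
      # include the exact leg endpoints so path length is conserved
      hh <- unique(c(t0, hh, t0 + s$hours))
      f <- pmin(1, pmax(0, (hh - t0) / s$hours))
      p <- .gc_point(wp$lat[s$idx], wp$lon[s$idx],
                     wp$lat[s$idx + 1], wp$lon[s$idx + 1], f)
      out[[length(out) + 1]] <- data.frame(
        hour = hh, lat = p$lat, lon = p$lon,
        altitude = plan$flight_altitude, phase = sprintf("leg%02d", s$idx))
    }
    t0 <- t0 + s$hours
  }
  x <- do.call(rbind, out)
  x <- x[order(x$hour), ]
  x <- x[c(TRUE, diff(x$hour) * 3600 > 1), ]  # drop sub-second duplicates
  track(time = plan$start_time + x$hour * 3600, lat = x$lat, lon = x$lon,
        quality_class = "TRUTH", bird_id = bird_id, species = species,
        tag_type = "ptt", altitude = x$altitude, phase = x$phase)
}

#' Duty-cycle on-window membership
#'
#' @param hours Numeric hours since track start.
#' @param duty_cycle `c(on, off)` hours.
#' @return Logical: within a transmitter on-window.
#' @export
duty_cycle_on <- function(hours, duty_cycle = c(on = 10, off = 48)) {
  period <- sum(duty_cycle)
  (hours %% period) < duty_cycle[[1]]
}

#' Degrade a truth track into Argos-style fixes
#'
#' Retains fixes inside the transmitter duty-cycle on-windows, samples an
#' Argos quality class per fix from a mixture, and displaces each fix by an
#' isotropic error drawn within its class radius. Solar tags also transmit
#' sparse low-quality fixes outside the schedule when fully charged; these
#' are emulated as `LOW`-class fixes every `aux_every_h` hours.
#'
#' @param truth A TRUTH `flytrack_track` at fine cadence.
#' @param plan The [simulation_plan()] (supplies duty cycle and seed).
#' @param class_mix Named probabilities over classes `G3`, `G2`, `G1`, `LOW`
#'   for in-window fixes.
#' @param cadence_h Fix cadence within on-windows (hours).
#' @param aux_every_h Cadence of charge-driven `LOW` fixes outside on-windows
#'   (hours); `NULL` disables them (strict duty cycling).
#' @return A `flytrack_track` of argos fixes.
#' @export
degrade_to_argos <- function(truth, plan,
                             class_mix = c(G3 = 0.3, G2 = 0.3, G1 = 0.3, LOW = 0.1),
                             cadence_h = 1, aux_every_h = 6) {
  stopifnot(inherits(truth, "flytrack_track"), inherits(plan, "flytrack_plan"))
  if (any(truth$quality_class != "TRUTH")) stop("expected a TRUTH track")
  set.seed(plan$seed + 1L)
  hrs <- as.numeric(difftime(truth$time, truth$time[1], units = "hours"))
  on <- duty_cycle_on(hrs, plan$duty_cycle)
  keep_on <- on & (hrs %% cadence_h) < 1e-9
  keep_aux <- if (is.null(aux_every_h)) rep(FALSE, length(hrs)) else
    (!on) & (hrs %% aux_every_h) < 1e-9
  idx <- which(keep_on | keep_aux)
  if (!length(idx)) {
    warning("duty cycle leaves no fixes; returning empty track")
    return(truth[0, ])
  }
  cls <- character(length(idx))
  cls[keep_aux[idx]] <- "LOW"
  n_on <- sum(keep_on[idx])
  cls[keep_on[idx]] <- sample(names(class_mix), n_on, replace = TRUE,
                              prob = class_mix)
  radius <- unname(.argos_classes[cls])
  ang <- stats::runif(length(idx), 0, 360)
  dist <- radius * sqrt(stats::runif(length(idx))) * 1000
  p <- geosphere::destPoint(cbind(truth$lon[idx], truth$lat[idx]), ang, dist,
                            r = 6371000)
  track(time = truth$time[idx], lat = p[, 2], lon = p[, 1],
        quality_class = cls, error_km = radius,
        bird_id = truth$bird_id[1], species = attr(truth, "species"),
        tag_type = "ptt",
        phase = if (!is.null(truth$phase)) truth$phase[idx] else NULL)
}

# linear interpolation of the truth path at arbitrary times
.interp_track <- function(truth, time) {
  tt <- as.numeric(truth$time)
  qq <- as.numeric(time)
  qq <- pmin(max(tt), pmax(min(tt), qq))
  data.frame(
    lat = stats::approx(tt, truth$lat, qq)$y,
    lon = stats::approx(tt, truth$lon, qq)$y,
    altitude = if (!is.null(truth$altitude))
      stats::approx(tt, truth$altitude, qq)$y else 0,
    flying = if (!is.null(truth$phase))
      grepl("^leg", truth$phase[pmax(1, findInterval(qq, tt))]) else FALSE)
}

#' Simulate geolocator light recordings
#'
#' Raw light every 5 minutes as a saturating logistic function of the solar
#' elevation at the bird's true position, with a dark floor. Shading can only
#' darken, so per-day gamma-distributed delays (minutes) push the morning
#' threshold crossing later and the evening crossing earlier.
#'
#' @param truth TRUTH track covering the requested interval.
#' @param plan The [simulation_plan()] (shading gamma, sun angle, seed).
#' @param step_min Sampling step in minutes.
#' @param shading Logical; `FALSE` gives noiseless light.
#' @return data.frame `time`, `light` (raw sensor units; the detection
#'   threshold is 1 on the log scale, i.e. light = e).
#' @export
simulate_light <- function(truth, plan, step_min = 5, shading = TRUE) {
  stopifnot(inherits(truth, "flytrack_track"), inherits(plan, "flytrack_plan"))
  set.seed(plan$seed + 2L)
  times <- seq(truth$time[1], truth$time[nrow(truth)], by = step_min * 60)
  pos <- .interp_track(truth, times)
  # local solar date & morning/afternoon split per sample
  st <- .solar_terms(times)
  tst <- (st$frac_hour * 60 + st$eqtime + 4 * pos$lon) %% 1440
  morning <- tst < 720
  local_date <- as.Date(times + pos$lon / 15 * 3600)
  days <- sort(unique(local_date))
  d_dawn <- stats::rgamma(length(days), plan$shading_shape, plan$shading_rate)
  d_dusk <- stats::rgamma(length(days), plan$shading_shape, plan$shading_rate)
  di <- match(local_date, days)
  shift_min <- if (shading) ifelse(morning, -d_dawn[di], d_dusk[di]) else 0
  el <- solar_position(times + shift_min * 60, pos$lat, pos$lon)$elevation
  light <- 1e-4 + 2 * exp(1) * stats::plogis((el - plan$sun_angle) / 1.5)
  data.frame(time = times, light = light)
}

# crude latitudinal surface climatology (deg C at sea level)
.surface_temp <- function(lat) 30 - 0.45 * pmax(0, abs(lat) - 5)

#' Simulate geolocator temperature blocks
#'
#' Temperature in 4-h blocks: the surface climatology at the bird's position
#' minus the standard atmospheric lapse of 6.5 degrees C per km of true
#' altitude, plus sensor noise, averaged within each block.
#'
#' @param truth TRUTH track with an `altitude` column (missing altitude is
#'   treated as sea level with a warning).
#' @param plan The [simulation_plan()].
#' @param block_h Block length in hours.
#' @param noise_sd Gaussian sensor noise (deg C).
#' @return data.frame `time` (block start), `temperature`.
#' @export
simulate_temperature <- function(truth, plan, block_h = 4, noise_sd = 0.5) {
  stopifnot(inherits(truth, "flytrack_track"), inherits(plan, "flytrack_plan"))
  set.seed(plan$seed + 3L)
  if (is.null(truth$altitude)) {
    warning("track has no altitude; assuming sea level")
    truth$altitude <- 0
  }
  starts <- seq(truth$time[1], truth$time[nrow(truth)], by = block_h * 3600)
  temp <- vapply(starts, function(s) {
    tt <- s + 3600 * (seq_len(block_h) - 0.5)
    pos <- .interp_track(truth, tt)
    mean(.surface_temp(pos$lat) - 6.5 * pos$altitude / 1000)
  }, numeric(1))
  data.frame(time = starts,
             temperature = temp + stats::rnorm(length(starts), 0, noise_sd))
}

#' Simulate geolocator wetness counts
#'
#' Hourly conductivity-switch counts in 0..14. Stationary (coastal foraging)
#' hours are wet with the plan's immersion probability; flight hours are
#' always dry.
#'
#' @param truth TRUTH track with phase labels.
#' @param plan The [simulation_plan()].
#' @return data.frame `time` (hour start), `wetness` (integer 0..14).
#' @export
simulate_wetness <- function(truth, plan) {
  stopifnot(inherits(truth, "flytrack_track"), inherits(plan, "flytrack_plan"))
  set.seed(plan$seed + 4L)
  starts <- seq(truth$time[1], truth$time[nrow(truth)], by = 3600)
  pos <- .interp_track(truth, starts + 1800)
  wet <- ifelse(pos$flying, 0L,
                stats::rbinom(length(starts), 14, plan$wet_prob))
  data.frame(time = starts, wetness = as.integer(wet))
}

#' Simulate a full geolocator stream
#'
#' Convenience wrapper bundling [simulate_light()], [simulate_temperature()]
#' and [simulate_wetness()] into one co-registered stream.
#'
#' @inheritParams simulate_light
#' @return List of class `flytrack_stream` with elements `light`,
#'   `temperature`, `wetness`.
#' @export
simulate_geolocator <- function(truth, plan, shading = TRUE) {
  structure(list(light = simulate_light(truth, plan, shading = shading),
                 temperature = simulate_temperature(truth, plan),
                 wetness = simulate_wetness(truth, plan)),
            class = "flytrack_stream")
}

#' Build a synthetic ridge DEM
#'
#' A regular lat/lon elevation grid with low plains and a configurable
#' east-west high ridge (a Himalaya-like barrier), with optional low passes
#' notched into the crest at stated longitudes.
#'
#' @param lat_range,lon_range Grid extent (degrees).
#' @param res Cell size (degrees).
#' @param base Plain elevation (masl).
#' @param crest Ridge crest elevation (masl).
#' @param ridge_lat,ridge_lat_sd Ridge centre latitude and Gaussian
#'   half-width (degrees).
#' @param ridge_lon Longitude span of the ridge.
#' @param passes Optional data.frame `lon`, `floor`, `width` describing low
#'   passes (crest lowered to `floor` masl over ~`width` degrees).
#' @return List of class `elevation_grid` with `lat`, `lon` (cell centres,
#'   ascending) and matrix `z` (rows = lat).
#' @export
make_dem <- function(lat_range = c(0, 45), lon_range = c(60, 120), res = 0.1,
                     base = 100, crest = 5500,
                     ridge_lat = 28.5, ridge_lat_sd = 1.2,
                     ridge_lon = c(75, 97), passes = NULL) {
  if (res <= 0) stop("resolution must be > 0")
  lat <- seq(lat_range[1] + res / 2, lat_range[2] - res / 2, by = res)
  lon <- seq(lon_range[1] + res / 2, lon_range[2] - res / 2, by = res)
  # crest profile along longitude: cosine-tapered ends, notched by passes
  ramp <- function(x) pmin(1, pmax(0, x))
  edge <- 2  # taper width, degrees
  prof <- crest * ramp((lon - ridge_lon[1]) / edge) * ramp((ridge_lon[2] - lon) / edge)
  if (!is.null(passes)) {
    for (k in seq_len(nrow(passes))) {
      notch <- exp(-((lon - passes$lon[k]) / passes$width[k])^2)
      prof <- pmin(prof, passes$floor[k] + (crest - passes$floor[k]) * (1 - notch))
    }
  }
  shape <- exp(-((lat - ridge_lat) / ridge_lat_sd)^2)
  z <- base + outer(shape, pmax(0, prof - base))
  structure(list(lat = lat, lon = lon, z = z, res = res), class = "elevation_grid")
}

#' Sample a DEM by bilinear interpolation
#'
#' @param dem An `elevation_grid`.
#' @param lat,lon Query points (degrees), vectorised.
#' @return Elevation (masl); `NA` outside the grid.
#' @export
dem_elevation <- function(dem, lat, lon) {
  stopifnot(inherits(dem, "elevation_grid"))
  bil <- function(ax, q) {
    i <- findInterval(q, ax)
    i <- pmin(pmax(i, 1), length(ax) - 1)
    f <- (q - ax[i]) / (ax[i + 1] - ax[i])
    list(i = i, f = pmin(1, pmax(0, f)))
  }
  ok <- lat >= dem$lat[1] & lat <= dem$lat[length(dem$lat)] &
    lon >= dem$lon[1] & lon <= dem$lon[length(dem$lon)]
  a <- bil(dem$lat, lat); b <- bil(dem$lon, lon)
  z <- dem$z[cbind(a$i, b$i)] * (1 - a$f) * (1 - b$f) +
    dem$z[cbind(a$i + 1, b$i)] * a$f * (1 - b$f) +
    dem$z[cbind(a$i, b$i + 1)] * (1 - a$f) * b$f +
    dem$z[cbind(a$i + 1, b$i + 1)] * a$f * b$f
  z[!ok] <- NA_real_
  z
}

#' Build a synthetic gridded wind field
#'
#' Winds (u eastward, v northward, km/h) on a lat/lon/time grid at the three
#' analysis levels (surface, 850 mb, 700 mb). Fields are a per-level mean
#' vector plus smooth low-order sinusoidal perturbations, seeded.
#'
#' @param lat_range,lon_range,res Spatial grid (degrees).
#' @param times POSIXct grid times.
#' @param mean_uv Named list per level of `c(u, v)` means (km/h).
#' @param perturb_sd Amplitude of the smooth perturbation (km/h); 0 gives a
#'   constant field.
#' @param seed Integer seed.
#' @return List of class `wind_field`.
#' @export
make_wind_field <- function(lat_range = c(0, 45), lon_range = c(60, 120), res = 1,
                            times = seq(as.POSIXct("2019-01-01", tz = "UTC"),
                                        by = "6 hours", length.out = 4),
                            mean_uv = list(surface = c(5, 2),
                                           mb850 = c(15, 5),
                                           mb700 = c(25, 8)),
                            perturb_sd = 0, seed = 1L) {
  if (res <= 0) stop("resolution must be > 0")
  stopifnot(all(c("surface", "mb850", "mb700") %in% names(mean_uv)))
  set.seed(seed)
  lat <- seq(lat_range[1], lat_range[2], by = res)
  lon <- seq(lon_range[1], lon_range[2], by = res)
  nt <- length(times)
  mk <- function(mu) {
    arr <- array(mu, dim = c(length(lat), length(lon), nt))
    if (perturb_sd > 0) {
      ph <- stats::runif(6, 0, 2 * pi)
      for (k in seq_len(nt)) {
        g <- outer(sin(2 * pi * lat / 30 + ph[1] + k / 3),
                   cos(2 * pi * lon / 40 + ph[2])) +
          outer(cos(2 * pi * lat / 17 + ph[3]),
                sin(2 * pi * lon / 23 + ph[4] + k / 5))
        arr[, , k] <- arr[, , k] + perturb_sd * g / sqrt(2)
      }
    }
    arr
  }
  levels <- lapply(mean_uv, function(m) list(u = mk(m[1]), v = mk(m[2])))
  structure(list(levels = levels, lat = lat, lon = lon, times = times),
            class = "wind_field")
}

#' Sample a wind field
#'
#' Bilinear interpolation in space, nearest-neighbour in time (mirroring
#' standard track-annotation services).
#'
#' @param wf A `wind_field`.
#' @param lat,lon Query position (degrees), vectorised.
#' @param time POSIXct query times.
#' @param level `"surface"`, `"mb850"` or `"mb700"`.
#' @return data.frame `u`, `v` (km/h); `NA` outside the grid.
#' @export
wind_at <- function(wf, lat, lon, time, level = "surface") {
  stopifnot(inherits(wf, "wind_field"), level %in% names(wf$levels))
  n <- max(length(lat), length(lon), length(time))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  time <- rep_len(as.POSIXct(time, tz = "UTC"), n)
  ti <- vapply(as.numeric(time), function(q)
    which.min(abs(as.numeric(wf$times) - q)), integer(1))
  bil <- function(ax, q) {
    i <- pmin(pmax(findInterval(q, ax), 1), length(ax) - 1)
    list(i = i, f = pmin(1, pmax(0, (q - ax[i]) / (ax[i + 1] - ax[i]))))
  }
  a <- bil(wf$lat, lat); b <- bil(wf$lon, lon)
  samp <- function(arr) {
    arr[cbind(a$i, b$i, ti)] * (1 - a$f) * (1 - b$f) +
      arr[cbind(a$i + 1, b$i, ti)] * a$f * (1 - b$f) +
      arr[cbind(a$i, b$i + 1, ti)] * (1 - a$f) * b$f +
      arr[cbind(a$i + 1, b$i + 1, ti)] * a$f * b$f
  }
  ok <- lat >= wf$lat[1] & lat <= wf$lat[length(wf$lat)] &
    lon >= wf$lon[1] & lon <= wf$lon[length(wf$lon)]
  u <- samp(wf$levels[[level]]$u); v <- samp(wf$levels[[level]]$v)
  u[!ok] <- NA_real_; v[!ok] <- NA_real_
  data.frame(u = u, v = v)
}
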