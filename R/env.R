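## Environmental annotation: wind support and airspeed at pressure levels,
## minimum-elevation profiles along routes, lapse-rate altitude inference.

#' Wind support and airspeed for flight legs
#'
#' For each leg, the wind is sampled at the leg midpoint (space and time)
#' at the requested pressure level; wind support is v_w cos(alpha), with
#' alpha the angle between the bird's track direction (initial great-circle
#' bearing) and the wind direction. Positive support is tailwind. Airspeed
#' is the scalar difference ground speed minus support (the crosswind
#' component is ignored; set `vector_airspeed = TRUE` for the full vector
#' subtraction).
#'
#' @param legs data.frame of legs as returned by [ground_speeds()] (columns
#'   `lat1`, `lon1`, `lat2`, `lon2`, `time1`, `time2`, `speed_kmh`).
#' @param wind_field A `wind_field`.
#' @param level `"surface"`, `"mb850"`, `"mb700"`, or `"max"` for the
#'   pointwise maximum signed support over the three levels.
#' @param vector_airspeed Logical; subtract the full wind vector instead of
#'   the along-track component.
#' @return `legs` with columns `level`, `wind_speed_kmh`, `alpha_deg`,
#'   `support_kmh`, `air_speed_kmh` appended (NA where the wind field does
#'   not cover the leg).
#' @export
wind_support <- function(legs, wind_field, level = "surface",
                         vector_airspeed = FALSE) {
  stopifnot(inherits(wind_field, "wind_field"))
  if (identical(level, "max")) {
    per <- lapply(c("surface", "mb850", "mb700"), function(lv)
      wind_support(legs, wind_field, lv, vector_airspeed))
    sup <- do.call(cbind, lapply(per, `[[`, "support_kmh"))
    pick <- max.col(replace(sup, is.na(sup), -Inf), ties.method = "first")
    out <- per[[1]]
    for (r in seq_len(nrow(out)))
      out[r, c("level", "wind_speed_kmh", "alpha_deg", "support_kmh",
               "air_speed_kmh")] <-
      per[[pick[r]]][r, c("level", "wind_speed_kmh", "alpha_deg",
                          "support_kmh", "air_speed_kmh")]
    out$level <- "max"
    return(out)
  }
  mid <- .gc_point_pairwise(legs$lat1, legs$lon1, legs$lat2, legs$lon2, 0.5)
  mid_t <- legs$time1 + as.numeric(difftime(legs$time2, legs$time1,
                                            units = "secs")) / 2
  w <- wind_at(wind_field, mid$lat, mid$lon, mid_t, level)
  brg <- geosphere::bearing(cbind(legs$lon1, legs$lat1),
                            cbind(legs$lon2, legs$lat2))
  brg_r <- brg * .deg2rad
  v_w <- sqrt(w$u^2 + w$v^2)
  support <- w$u * sin(brg_r) + w$v * cos(brg_r)     # = v_w cos(alpha)
  alpha <- acos(pmin(1, pmax(-1, ifelse(v_w > 0, support / v_w, 1)))) * .rad2deg
  air <- if (vector_airspeed) {
    cross <- w$u * cos(brg_r) - w$v * sin(brg_r)
    sqrt((legs$speed_kmh - support)^2 + cross^2)
  } else legs$speed_kmh - support
  legs$level <- level
  legs$wind_speed_kmh <- v_w
  legs$alpha_deg <- alpha
  legs$support_kmh <- support
  legs$air_speed_kmh <- air
  legs
}

# .gc_point for paired endpoint vectors
.gc_point_pairwise <- function(lat1, lon1, lat2, lon2, f) {
  n <- length(lat1)
  out <- data.frame(lat = numeric(n), lon = numeric(n))
  for (i in seq_len(n)) {
    if (abs(lat1[i] - lat2[i]) < 1e-12 && abs(lon1[i] - lon2[i]) < 1e-12) {
      out$lat[i] <- lat1[i]; out$lon[i] <- lon1[i]
    } else {
      p <- .gc_point(lat1[i], lon1[i], lat2[i], lon2[i], f)
      out$lat[i] <- p$lat; out$lon[i] <- p$lon
    }
  }
  out
}

#' Minimum-elevation profile along a route
#'
#' The route is densified by great-circle interpolation (step <=
#' `step_deg`, fine enough that sampling error is below the DEM's own cell
#' variation), the DEM sampled along it, and the minimum elevation taken in
#' every `bin_deg` latitude bin (half-open bins [x, x + bin)). The profile
#' mean is the equal-weight mean over bins, the per-individual summary
#' statistic.
#'
#' @param track A `flytrack_track`.
#' @param dem An `elevation_grid`.
#' @param bin_deg Latitude bin width (degrees).
#' @param step_deg Densification step (degrees).
#' @return List with `profile` (data.frame `lat_bin` lower edge, `min_masl`)
#'   and `mean_masl`; bins the DEM does not cover carry `NA`.
#' @export
min_elevation_profile <- function(track, dem, bin_deg = 0.1, step_deg = 0.01) {
  stopifnot(inherits(track, "flytrack_track"), inherits(dem, "elevation_grid"))
  path <- .densify_path(track, step_deg)
  elev <- dem_elevation(dem, path$lat, path$lon)
  bin <- floor(path$lat / bin_deg) * bin_deg
  agg <- tapply(elev, bin, function(z)
    if (all(is.na(z))) NA_real_ else min(z, na.rm = TRUE))
  profile <- data.frame(lat_bin = as.numeric(names(agg)),
                        min_masl = as.numeric(agg))
  profile <- profile[order(profile$lat_bin), ]
  rownames(profile) <- NULL
  list(profile = profile, mean_masl = mean(profile$min_masl, na.rm = TRUE))
}

#' Flight altitude inferred from tag temperature
#'
#' The drop of geolocator temperature below the pre-departure baseline (mean
#' over the last 24 h before departure), converted to altitude with the
#' standard atmospheric lapse rate: altitude = deltaT / lapse.
#'
#' @param temperature data.frame `time` (block start), `temperature` (deg C)
#'   in 4-h blocks.
#' @param departure POSIXct departure instant (e.g. from
#'   [detect_departure_from_wetness()]).
#' @param lapse_c_per_km Lapse rate (deg C per km).
#' @param baseline_h Baseline window before departure (hours).
#' @return data.frame for post-departure blocks: `time`, `delta_t_c`,
#'   `altitude_m`; attribute `baseline_c`.
#' @export
altitude_from_temperature <- function(temperature, departure,
                                      lapse_c_per_km = 6.5, baseline_h = 24) {
  stopifnot(all(c("time", "temperature") %in% names(temperature)))
  pre <- temperature$time < departure &
    temperature$time >= departure - baseline_h * 3600
  if (!any(pre)) stop("no pre-departure temperature blocks for the baseline")
  baseline <- mean(temperature$temperature[pre])
  post <- temperature[temperature$time >= departure, , drop = FALSE]
  delta <- baseline - post$temperature
  out <- data.frame(time = post$time, delta_t_c = delta,
                    altitude_m = delta / lapse_c_per_km * 1000)
  attr(out, "baseline_c") <- baseline
  out
}
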