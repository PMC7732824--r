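## Rule-based segmentation: stopovers, wetness-derived departures, seasonal
## phases, and barrier crossings over a DEM mask.

.SGT <- 8 * 3600  # reporting offset: Singapore Time, UTC+8

#' Detect stopovers in a track
#'
#' A stopover is a maximal run of fixes all within `radius_km` of the running
#' centroid, spanning at least `min_days`, preceded and followed by
#' directional movements greater than `radius_km`. Because fixes are duty
#' cycled, the minimum-duration test is applied to the outer bracket of the
#' residency (from the last distant fix before arrival to the first distant
#' fix after departure), which can never under-cover the true residency;
#' reported arrival and departure are the midpoints of the bracketing fix
#' gaps. Residencies containing the first or last fix are reported separately
#' as terminal residencies (non-breeding / breeding sites), not stopovers.
#'
#' @param track A `flytrack_track`.
#' @param radius_km Residency radius; 150 km is the working error scale of
#'   the tracking methods.
#' @param min_days Minimum stopover duration (days); shorter pauses are
#'   invisible to the duty-cycled tags and are never reported.
#' @return List with data.frames `stopovers` and `residencies`, each with
#'   `lat`, `lon` (centroid), `arrival`, `departure` (POSIXct UTC),
#'   `duration_days`, `first_fix`, `last_fix` (row indices).
#' @export
detect_stopovers <- function(track, radius_km = 150, min_days = 3) {
  stopifnot(inherits(track, "flytrack_track"))
  n <- nrow(track)
  runs <- list()
  i <- 1
  while (i <= n) {
    # grow a run while every new fix stays within radius of the running centroid
    j <- i
    clat <- track$lat[i]; clon <- track$lon[i]
    while (j < n) {
      d <- geosphere::distHaversine(c(clon, clat),
                                    c(track$lon[j + 1], track$lat[j + 1]), r = 6371)
      if (d > radius_km) break
      j <- j + 1
      clat <- mean(track$lat[i:j]); clon <- mean(track$lon[i:j])
    }
    runs[[length(runs) + 1]] <- list(i = i, j = j, lat = clat, lon = clon)
    i <- j + 1
  }
  rows <- lapply(runs, function(r) {
    # outer bracket: last fix before arrival .. first fix after departure
    t_in <- track$time[r$i]; t_out <- track$time[r$j]
    t_pre <- if (r$i > 1) track$time[r$i - 1] else t_in
    t_post <- if (r$j < n) track$time[r$j + 1] else t_out
    arrival <- t_pre + as.numeric(difftime(t_in, t_pre, units = "secs")) / 2
    departure <- t_out + as.numeric(difftime(t_post, t_out, units = "secs")) / 2
    outer_days <- as.numeric(difftime(t_post, t_pre, units = "days"))
    data.frame(lat = r$lat, lon = r$lon, arrival = arrival,
               departure = departure,
               duration_days = as.numeric(difftime(departure, arrival,
                                                   units = "days")),
               outer_days = outer_days, first_fix = r$i, last_fix = r$j)
  })
  rows <- do.call(rbind, rows)
  terminal <- rows$first_fix == 1 | rows$last_fix == n
  long_enough <- rows$outer_days >= min_days
  # flanking displacement > radius_km (guaranteed by run construction except
  # at track ends, which are terminal anyway)
  stop_rows <- rows[long_enough & !terminal, , drop = FALSE]
  res_rows <- rows[long_enough & terminal, , drop = FALSE]
  drop <- function(x) { x$outer_days <- NULL; rownames(x) <- NULL; x }
  list(stopovers = drop(stop_rows), residencies = drop(res_rows))
}

#' Departure time from wetness counts
#'
#' Coastal shorebirds are immersed while foraging and dry in flight: the bird
#' is taken to depart at the end of the last hour showing wetness > 0 before
#' a sustained dry run.
#'
#' @param wetness data.frame `time` (hour start), `wetness` (0..14).
#' @param dry_run_h Minimum sustained dry spell (hours) that marks a
#'   departure.
#' @return POSIXct departure instant, or `NULL` when no qualifying dry run
#'   exists.
#' @export
detect_departure_from_wetness <- function(wetness, dry_run_h = 12) {
  stopifnot(all(c("time", "wetness") %in% names(wetness)))
  wet <- wetness$wetness > 0
  if (!any(wet)) return(NULL)
  r <- rle(!wet)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= dry_run_h && starts[k] > 1) {
      return(wetness$time[starts[k] - 1] + 3600)  # end of last wet hour
    }
  }
  NULL
}

#' Assign seasonal migration phases
#'
#' The residency containing the deployment (first fix) is the non-breeding
#' period; the northernmost residency at or above `breeding_lat` is the
#' breeding period; the intervals between are northward and southward
#' migration. Birds with no residency reaching the breeding latitude are
#' flagged as partial migrants (sub-adult behaviour) and get no breeding
#' phase.
#'
#' @param track A `flytrack_track`.
#' @param segments Output of [detect_stopovers()].
#' @param breeding_lat Minimum breeding latitude (degrees N); 30 suits
#'   plateau-breeding Redshanks, 60 Russian-breeding Whimbrels.
#' @return List with `phases` (data.frame `phase`, `start`, `end`) and
#'   `partial` (logical).
#' @export
assign_phases <- function(track, segments, breeding_lat = 30) {
  res <- rbind(segments$residencies, segments$stopovers)
  n <- nrow(track)
  dep <- res[res$first_fix == 1, , drop = FALSE]
  if (!nrow(dep)) stop("no residency at the deployment site")
  breed_cand <- res[res$lat >= breeding_lat & res$first_fix > 1, , drop = FALSE]
  if (!nrow(breed_cand)) {
    return(list(phases = data.frame(phase = "nonbreeding",
                                    start = track$time[1],
                                    end = track$time[n]),
                partial = TRUE))
  }
  breed <- breed_cand[which.max(breed_cand$lat), ]
  ph <- data.frame(
    phase = c("nonbreeding", "northward", "breeding"),
    start = c(track$time[1], dep$departure[1], breed$arrival),
    end = c(dep$departure[1], breed$arrival, breed$departure))
  if (breed$last_fix < n) {
    ret <- res[res$last_fix == n & res$first_fix > breed$last_fix, , drop = FALSE]
    south_end <- if (nrow(ret)) ret$arrival[1] else track$time[n]
    ph <- rbind(ph, data.frame(phase = "southward", start = breed$departure,
                               end = south_end))
    if (nrow(ret))
      ph <- rbind(ph, data.frame(phase = "nonbreeding_return",
                                 start = ret$arrival[1], end = track$time[n]))
  }
  list(phases = ph, partial = FALSE)
}

#' Detect barrier crossings over a high-elevation mask
#'
#' Reports each passage of the track over the contiguous region of the DEM
#' at or above `crest_elevation`: entry/exit longitudes and dates, and the
#' direction of travel. Routes that never intersect the mask (eastern
#' detours) return an empty frame.
#'
#' @param track A `flytrack_track`.
#' @param dem An `elevation_grid`.
#' @param crest_elevation Mask threshold (masl).
#' @param step_deg Densification step along the path (degrees).
#' @return data.frame `direction` (`"north"`/`"south"`), `lon_entry`,
#'   `lon_exit`, `date_entry`, `date_exit` (SGT dates).
#' @export
detect_barrier_crossing <- function(track, dem, crest_elevation = 4000,
                                    step_deg = 0.05) {
  stopifnot(inherits(track, "flytrack_track"), inherits(dem, "elevation_grid"))
  path <- .densify_path(track, step_deg)
  elev <- dem_elevation(dem, path$lat, path$lon)
  over <- !is.na(elev) & elev >= crest_elevation
  if (!any(over)) {
    return(data.frame(direction = character(), lon_entry = numeric(),
                      lon_exit = numeric(),
                      date_entry = as.Date(character()),
                      date_exit = as.Date(character())))
  }
  r <- rle(over)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    i1 <- starts[k]; i2 <- ends[k]
    dirn <- if (path$lat[i2] >= path$lat[i1]) "north" else "south"
    out[[length(out) + 1]] <- data.frame(
      direction = dirn,
      lon_entry = path$lon[i1], lon_exit = path$lon[i2],
      date_entry = as.Date(path$time[i1] + .SGT),
      date_exit = as.Date(path$time[i2] + .SGT))
  }
  do.call(rbind, out)
}

# densify a track along great-circle legs to a maximum angular step
.densify_path <- function(track, step_deg = 0.05) {
  out <- list()
  n <- nrow(track)
  for (i in seq_len(n - 1)) {
    d_deg <- geosphere::distHaversine(c(track$lon[i], track$lat[i]),
                                      c(track$lon[i + 1], track$lat[i + 1]),
                                      r = 6371) / 111.2
    m <- max(1, ceiling(d_deg / step_deg))
    f <- seq(0, 1, length.out = m + 1)[-(m + 1)]
    p <- if (d_deg < 1e-9)
      data.frame(lat = rep(track$lat[i], length(f)),
                 lon = rep(track$lon[i], length(f)))
    else .gc_point(track$lat[i], track$lon[i],
                   track$lat[i + 1], track$lon[i + 1], f)
    tt <- track$time[i] + f * as.numeric(difftime(track$time[i + 1],
                                                  track$time[i], units = "secs"))
    out[[i]] <- data.frame(lat = p$lat, lon = p$lon, time = tt)
  }
  out[[n]] <- data.frame(lat = track$lat[n], lon = track$lon[n],
                         time = track$time[n])
  do.call(rbind, out)
}
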