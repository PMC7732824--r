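## Migration metrics: great-circle distances, detours, ground speeds with
## error propagation, and the per-season timing/distance summary table.

#' Great-circle distance
#'
#' Spherical (haversine) distance with Earth radius 6371.0 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised).
#' @return Distance in km.
#' @examples
#' great_circle_km(1.45, 103.73, 1.41, 103.99)  # ~29 km
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Minimum migration distance within a phase
#'
#' Sum of great-circle legs through the retained fixes and stopover
#' centroids inside the phase window; with duty-cycled tags this is the
#' minimum flight distance, not the full flown path.
#'
#' @param track A `flytrack_track`.
#' @param stopovers Stopover frame from [detect_stopovers()] (may be empty);
#'   fixes belonging to a stopover are replaced by its centroid.
#' @param start,end POSIXct phase bounds.
#' @param from,to Optional `c(lat, lon)` route endpoints (typically the
#'   non-breeding and breeding residency centroids), prepended/appended so
#'   duty-cycle gaps at the phase edges do not drop distance.
#' @return Distance in km.
#' @export
migration_distance <- function(track, stopovers = NULL, start = min(track$time),
                               end = max(track$time), from = NULL, to = NULL) {
  sel <- track$time >= start & track$time <= end
  pts <- data.frame(lat = track$lat[sel], lon = track$lon[sel])
  if (!is.null(stopovers) && nrow(stopovers)) {
    tt <- track$time[sel]
    member <- rep(NA_integer_, nrow(pts))
    for (k in seq_len(nrow(stopovers)))
      member[tt >= stopovers$arrival[k] & tt <= stopovers$departure[k]] <- k
    pts$lat[!is.na(member)] <- stopovers$lat[member[!is.na(member)]]
    pts$lon[!is.na(member)] <- stopovers$lon[member[!is.na(member)]]
    keep <- c(TRUE, !(diff(member) == 0 & !is.na(member[-1]) & !is.na(member[-length(member)])))
    keep[is.na(keep)] <- TRUE
    pts <- pts[keep, ]
  }
  if (!is.null(from)) pts <- rbind(data.frame(lat = from[1], lon = from[2]), pts)
  if (!is.null(to)) pts <- rbind(pts, data.frame(lat = to[1], lon = to[2]))
  if (nrow(pts) < 2) return(0)
  sum(great_circle_km(pts$lat[-nrow(pts)], pts$lon[-nrow(pts)],
                      pts$lat[-1], pts$lon[-1]))
}

#' Migration detour
#'
#' Extra track length above the straight-line (great-circle) distance
#' between the phase endpoints, e.g. non-breeding to breeding centroids.
#'
#' @inheritParams migration_distance
#' @param from,to `c(lat, lon)` of the endpoint residencies.
#' @return Detour in km (non-negative up to estimation noise).
#' @export
detour_km <- function(track, stopovers = NULL, start = min(track$time),
                      end = max(track$time),
                      from = c(track$lat[1], track$lon[1]),
                      to = c(track$lat[nrow(track)], track$lon[nrow(track)])) {
  migration_distance(track, stopovers, start, end) -
    great_circle_km(from[1], from[2], to[1], to[2])
}

#' Ground speeds between consecutive fixes
#'
#' Speed over each leg between consecutive fixes less than `max_gap_h`
#' apart; the speed error sums the two error radii over the flying time.
#' Legs slower than `min_kmh` may hide undetected stopovers within the duty
#' cycle and are not retained.
#'
#' @param track A `flytrack_track`.
#' @param min_kmh Retention threshold (km/h).
#' @param max_gap_h Maximum leg duration (hours); longer gaps span the duty
#'   cycle's off period.
#' @return data.frame with leg endpoints (`time1`, `time2`, `lat1`, `lon1`,
#'   `lat2`, `lon2`), `distance_km`, `dt_h`, `speed_kmh`, `speed_error_kmh`,
#'   `retained`.
#' @export
ground_speeds <- function(track, min_kmh = 20, max_gap_h = 24) {
  n <- nrow(track)
  i <- seq_len(n - 1)
  dt_h <- as.numeric(difftime(track$time[-1], track$time[-n], units = "hours"))
  d <- great_circle_km(track$lat[-n], track$lon[-n], track$lat[-1], track$lon[-1])
  out <- data.frame(time1 = track$time[-n], time2 = track$time[-1],
                    lat1 = track$lat[-n], lon1 = track$lon[-n],
                    lat2 = track$lat[-1], lon2 = track$lon[-1],
                    distance_km = d, dt_h = dt_h,
                    speed_kmh = d / dt_h,
                    speed_error_kmh = (track$error_km[-n] + track$error_km[-1]) / dt_h)
  out <- out[out$dt_h <= max_gap_h, ]
  out$retained <- out$speed_kmh >= min_kmh
  rownames(out) <- NULL
  out
}

# whole-day difference between two instants on the SGT calendar
.sgt_days <- function(from, to) {
  as.numeric(as.Date(to + .SGT) - as.Date(from + .SGT))
}

#' Format an instant as an SGT calendar date
#'
#' @param time POSIXct (UTC).
#' @return `Date` in Singapore Time (UTC+8), the reporting calendar.
#' @export
sgt_date <- function(time) as.Date(time + .SGT)

#' Summarise a migration season
#'
#' One row of the standard migration table for one direction: departure and
#' arrival dates (SGT calendar), stopover count and days, whole days
#' travelling, and minimum migration distance.
#'
#' @param track A `flytrack_track`.
#' @param stopovers Stopovers within the phase (frame from
#'   [detect_stopovers()], possibly empty).
#' @param depart,arrive POSIXct phase bounds (departure from the origin
#'   residency, arrival at the destination residency).
#' @param direction Label (`"north"` / `"south"`).
#' @return One-row data.frame: `direction`, `depart_sgt`, `n_stopovers`,
#'   `days_at_stopovers`, `arrive_sgt`, `days_travelling`,
#'   `migration_distance_km`.
#' @export
summarise_migration <- function(track, stopovers, depart, arrive,
                                direction = "north") {
  in_phase <- if (nrow(stopovers))
    stopovers[stopovers$arrival >= depart & stopovers$departure <= arrive, ,
              drop = FALSE]
  else stopovers
  days_stop <- if (nrow(in_phase))
    sum(.sgt_days(in_phase$arrival, in_phase$departure)) else 0
  data.frame(direction = direction,
             depart_sgt = sgt_date(depart),
             n_stopovers = nrow(in_phase),
             days_at_stopovers = days_stop,
             arrive_sgt = sgt_date(arrive),
             days_travelling = .sgt_days(depart, arrive),
             migration_distance_km = migration_distance(track, in_phase,
                                                        depart, arrive))
}
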