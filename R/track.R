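## Track container: a data.frame of timestamped fixes with per-fix error radii.

.argos_classes <- c(G3 = 0.25, G2 = 0.5, G1 = 1.5, LOW = 5, TRUTH = 0)

#' Construct a track
#'
#' A track is an ordered set of timestamped geographic fixes with per-fix
#' error radii and an Argos-style quality class. `TRUTH` fixes (simulation
#' ground truth) carry zero error.
#'
#' @param time POSIXct (UTC) fix times, strictly increasing.
#' @param lat,lon Coordinates in decimal degrees; `lon` in (-180, 180].
#' @param quality_class Character, one of `"G3"`, `"G2"`, `"G1"`, `"LOW"`,
#'   `"TRUTH"` (Argos classes 3/2/1, below-1, and simulation truth).
#' @param error_km Error radius per fix (km). Defaults to the nominal radius
#'   of the quality class: 0.25, 0.5, 1.5, 5 and 0 km respectively.
#' @param bird_id Individual identifier.
#' @param species,tag_type Track metadata (free-form; `tag_type` normally
#'   `"ptt"` or `"geolocator"`).
#' @param altitude Optional true altitude (masl) per fix, simulation only.
#' @param phase Optional per-fix phase label (simulation ground truth).
#' @return A data.frame of class `flytrack_track`.
#' @export
track <- function(time, lat, lon, quality_class = "TRUTH", error_km = NULL,
                  bird_id = "bird1", species = "other", tag_type = "ptt",
                  altitude = NULL, phase = NULL) {
  time <- as.POSIXct(time, tz = "UTC")
  n <- length(time)
  if (n < 2) stop("a track needs at least 2 fixes")
  if (any(diff(as.numeric(time)) <= 0))
    stop("fix timestamps must be strictly increasing")
  if (any(lat < -90 | lat > 90)) stop("latitude out of [-90, 90]")
  if (any(lon <= -180 | lon > 180)) stop("longitude out of (-180, 180]")
  quality_class <- rep_len(as.character(quality_class), n)
  bad <- setdiff(unique(quality_class), names(.argos_classes))
  if (length(bad)) stop("unknown quality class: ", paste(bad, collapse = ", "))
  if (is.null(error_km)) error_km <- unname(.argos_classes[quality_class])
  if (any(error_km < 0)) stop("error_km must be >= 0")
  x <- data.frame(bird_id = rep_len(bird_id, n), time = time,
                  lat = as.numeric(lat), lon = as.numeric(lon),
                  quality_class = quality_class, error_km = error_km)
  if (!is.null(altitude)) x$altitude <- rep_len(as.numeric(altitude), n)
  if (!is.null(phase)) x$phase <- rep_len(as.character(phase), n)
  structure(x, species = species, tag_type = tag_type,
            class = c("flytrack_track", "data.frame"))
}

#' Coerce a data.frame of fixes to a track
#'
#' @param x data.frame with at least `time`, `lat`, `lon` columns.
#' @param ... Passed to [track()].
#' @export
as_track <- function(x, ...) {
  args <- list(time = x$time, lat = x$lat, lon = x$lon, ...)
  if (!is.null(x$quality_class) && is.null(args$quality_class))
    args$quality_class <- x$quality_class
  if (!is.null(x$error_km) && is.null(args$error_km)) args$error_km <- x$error_km
  if (!is.null(x$bird_id) && is.null(args$bird_id)) args$bird_id <- x$bird_id[1]
  if (!is.null(x$altitude) && is.null(args$altitude)) args$altitude <- x$altitude
  if (!is.null(x$phase) && is.null(args$phase)) args$phase <- x$phase
  do.call(track, args)
}

#' @export
print.flytrack_track <- function(x, ...) {
  cat(sprintf("<flytrack_track> %s (%s, %s): %d fixes, %s .. %s\n",
              x$bird_id[1], attr(x, "species"), attr(x, "tag_type"), nrow(x),
              format(min(x$time)), format(max(x$time))))
  cat(sprintf("  lat %.2f..%.2f, lon %.2f..%.2f, classes: %s\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon),
              paste(names(table(x$quality_class)), collapse = "/")))
  invisible(x)
}
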