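## File formats: Movebank-style track CSV, geolocator stream CSVs, ESRI
## ASCII DEM, long-format gridded wind CSV, GeoJSON export.

.ts_fmt <- "%Y-%m-%dT%H:%M:%SZ"

#' Write / read a Movebank-style track CSV
#'
#' Columns `timestamp` (ISO-8601 UTC, to the second), `location-lat`,
#' `location-long` (1e-6 degree), `argos:lc`, `error-km`,
#' `individual-local-identifier`. The round trip is lossless at that
#' precision.
#'
#' @param track A `flytrack_track`.
#' @param path Output file.
#' @return `write_track_csv` returns `path` invisibly; `read_track_csv`
#'   returns a `flytrack_track`.
#' @export
write_track_csv <- function(track, path) {
  stopifnot(inherits(track, "flytrack_track"))
  df <- data.frame(
    timestamp = format(track$time, .ts_fmt, tz = "UTC"),
    `location-lat` = sprintf("%.6f", track$lat),
    `location-long` = sprintf("%.6f", track$lon),
    `argos:lc` = track$quality_class,
    `error-km` = track$error_km,
    `individual-local-identifier` = track$bird_id,
    check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(timestamp = "character"))
  need <- c("timestamp", "location-lat", "location-long")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  tt <- as.POSIXct(df$timestamp, format = .ts_fmt, tz = "UTC")
  if (anyNA(tt)) {
    bad <- which(is.na(tt))[1]
    stop(sprintf("%s: malformed timestamp at data row %d ('%s')",
                 path, bad, df$timestamp[bad]))
  }
  track(time = tt, lat = df$`location-lat`, lon = df$`location-long`,
        quality_class = if (!is.null(df$`argos:lc`)) df$`argos:lc` else "TRUTH",
        error_km = df$`error-km`,
        bird_id = if (!is.null(df$`individual-local-identifier`))
          df$`individual-local-identifier`[1] else "bird1")
}

#' Write / read geolocator stream CSVs
#'
#' Two-column CSVs (`timestamp`, value) for light, temperature and wetness,
#' the formats produced by the synthetic generators and accepted by the
#' geolocation chain. `read_light_csv` also accepts Migrate-Technology-style
#' two-column text.
#'
#' @param x data.frame with `time` and a value column.
#' @param path File path.
#' @export
write_stream_csv <- function(x, path) {
  val <- setdiff(names(x), "time")[1]
  df <- data.frame(timestamp = format(x$time, .ts_fmt, tz = "UTC"),
                   value = x[[val]])
  names(df)[2] <- val
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
read_light_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  names(df)[1:2] <- c("timestamp", "light")
  tt <- as.POSIXct(df$timestamp, format = .ts_fmt, tz = "UTC")
  if (anyNA(tt)) tt <- as.POSIXct(df$timestamp, tz = "UTC")
  if (anyNA(tt)) stop(sprintf("%s: unparseable timestamps", path))
  data.frame(time = tt, light = as.numeric(df$light))
}

#' Write / read an ESRI ASCII grid DEM
#'
#' Standard ncols/nrows/xllcorner/yllcorner/cellsize header followed by the
#' elevation matrix, north row first; 0-based grid indexing from the
#' south-west corner, cell-centre registration.
#'
#' @param dem An `elevation_grid`.
#' @param path File path.
#' @export
write_dem_ascii <- function(dem, path) {
  stopifnot(inherits(dem, "elevation_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", length(dem$lon)),
               sprintf("nrows %d", length(dem$lat)),
               sprintf("xllcorner %.6f", dem$lon[1] - dem$res / 2),
               sprintf("yllcorner %.6f", dem$lat[1] - dem$res / 2),
               sprintf("cellsize %.6f", dem$res),
               "NODATA_value -9999"), con)
  for (r in rev(seq_along(dem$lat)))
    writeLines(paste(sprintf("%.2f", dem$z[r, ]), collapse = " "), con)
  invisible(path)
}

#' @rdname write_dem_ascii
#' @export
read_dem_ascii <- function(path) {
  hdr <- utils::read.table(path, nrows = 6,
                           col.names = c("key", "value"),
                           colClasses = c("character", "numeric"))
  h <- stats::setNames(hdr$value, tolower(hdr$key))
  z <- as.matrix(utils::read.table(path, skip = 6))
  if (nrow(z) != h["nrows"] || ncol(z) != h["ncols"])
    stop(sprintf("%s: grid is %dx%d but header says %dx%d", path,
                 nrow(z), ncol(z), h["nrows"], h["ncols"]))
  z[z == h["nodata_value"]] <- NA
  res <- h[["cellsize"]]
  structure(list(
    lat = h[["yllcorner"]] + res / 2 + res * (seq_len(nrow(z)) - 1),
    lon = h[["xllcorner"]] + res / 2 + res * (seq_len(ncol(z)) - 1),
    z = z[rev(seq_len(nrow(z))), , drop = FALSE], res = res),
    class = "elevation_grid")
}

#' Write / read a gridded wind field as long-format CSV
#'
#' One row per (level, time, lat, lon) cell with u and v components (km/h),
#' a plain-text stand-in for gridded reanalysis exports.
#'
#' @param wf A `wind_field`.
#' @param path File path.
#' @export
write_wind_csv <- function(wf, path) {
  stopifnot(inherits(wf, "wind_field"))
  rows <- list()
  for (lv in names(wf$levels)) {
    g <- expand.grid(lat = wf$lat, lon = wf$lon, ti = seq_along(wf$times))
    rows[[lv]] <- data.frame(
      level = lv, timestamp = format(wf$times[g$ti], .ts_fmt, tz = "UTC"),
      lat = g$lat, lon = g$lon,
      u = as.vector(wf$levels[[lv]]$u), v = as.vector(wf$levels[[lv]]$v))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_wind_csv
#' @export
read_wind_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("level", "timestamp", "lat", "lon", "u", "v")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  df$time <- as.POSIXct(df$timestamp, format = .ts_fmt, tz = "UTC")
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  times <- sort(unique(df$time))
  levels <- list()
  for (lv in unique(df$level)) {
    s <- df[df$level == lv, ]
    u <- array(NA_real_, c(length(lat), length(lon), length(times)))
    v <- u
    idx <- cbind(match(s$lat, lat), match(s$lon, lon), match(s$time, times))
    u[idx] <- s$u; v[idx] <- s$v
    levels[[lv]] <- list(u = u, v = v)
  }
  structure(list(levels = levels, lat = lat, lon = lon,
                 times = as.POSIXct(times, tz = "UTC", origin = "1970-01-01")),
            class = "wind_field")
}

#' Export a track or located path as a GeoJSON LineString
#'
#' @param x A `flytrack_track` or `flytrack_located` frame (columns
#'   `lat`/`lon`).
#' @param path File path.
#' @param properties Optional named list written as feature properties.
#' @export
write_geojson <- function(x, path, properties = list()) {
  coords <- lapply(seq_len(nrow(x)), function(i) c(x$lon[i], x$lat[i]))
  gj <- list(type = "FeatureCollection",
             features = list(list(
               type = "Feature",
               geometry = list(type = "LineString", coordinates = coords),
               properties = properties)))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
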