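## Low-precision solar ephemeris (NOAA General Solar Position series).
## Accuracy ~0.1 deg in elevation, ample for a ~150 km geolocation error scale.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

# fractional year (radians) and derived series, vectorised over POSIXct
.solar_terms <- function(time) {
  lt <- as.POSIXlt(time, tz = "UTC")
  doy <- lt$yday + 1
  frac_hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  ndays <- ifelse((lt$year + 1900) %% 4 == 0 &
                    ((lt$year + 1900) %% 100 != 0 | (lt$year + 1900) %% 400 == 0),
                  366, 365)
  g <- 2 * pi / ndays * (doy - 1 + (frac_hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  list(eqtime = eqtime, decl = decl, frac_hour = frac_hour)
}

#' Solar position
#'
#' Solar elevation and azimuth at given times and locations, from the standard
#' low-precision (NOAA) solar ephemeris. Elevation accuracy is about 0.1
#' degrees, far below the working error of light-level geolocation.
#'
#' @param time POSIXct (UTC) times.
#' @param lat,lon Position in decimal degrees (north / east).
#' @return A data.frame with columns `elevation` and `azimuth` (degrees;
#'   azimuth clockwise from north).
#' @examples
#' solar_position(as.POSIXct("2020-03-20 12:00", tz = "UTC"), 0, 0)
#' @export
solar_position <- function(time, lat, lon) {
  st <- .solar_terms(time)
  tst <- (st$frac_hour * 60 + st$eqtime + 4 * lon) %% 1440  # true solar time, min
  ha <- (tst / 4) - 180                                     # hour angle, deg
  ha_r <- ha * .deg2rad
  lat_r <- lat * .deg2rad
  sin_el <- sin(lat_r) * sin(st$decl) + cos(lat_r) * cos(st$decl) * cos(ha_r)
  sin_el <- pmin(1, pmax(-1, sin_el))
  el <- asin(sin_el)
  cos_az <- (sin(st$decl) - sin(lat_r) * sin_el) / (cos(lat_r) * cos(el))
  cos_az <- pmin(1, pmax(-1, cos_az))
  az <- acos(cos_az) * .rad2deg
  az <- ifelse(ha > 0, 360 - az, az)
  data.frame(elevation = el * .rad2deg, azimuth = az)
}

#' Predicted twilight time for a sun elevation threshold
#'
#' Time at which the sun crosses a given elevation angle on a given date at a
#' given site, the forward model inverted by the threshold method.
#'
#' @param date Date (UTC civil date) or POSIXct from which the date is taken.
#' @param lat,lon Site in decimal degrees.
#' @param angle Sun elevation angle in degrees (typically negative).
#' @param rise Logical; `TRUE` for the morning (upward) crossing.
#' @return POSIXct (UTC) crossing time, `NA` where the sun never crosses the
#'   angle that day (polar day/night at that threshold).
#' @export
twilight_time <- function(date, lat, lon, angle, rise = TRUE) {
  date <- as.Date(date)
  # evaluate ephemeris terms near local noon of that date
  approx_noon <- as.POSIXct(paste(format(date), "12:00:00"), tz = "UTC") -
    as.difftime(lon / 15, units = "hours")
  st <- .solar_terms(approx_noon)
  lat_r <- lat * .deg2rad
  cos_ha <- (sin(angle * .deg2rad) - sin(lat_r) * sin(st$decl)) /
    (cos(lat_r) * cos(st$decl))
  ha <- acos(pmin(1, pmax(-1, cos_ha))) * .rad2deg
  ha[cos_ha > 1 | cos_ha < -1] <- NA_real_
  sign <- if (rise) 1 else -1
  minutes <- 720 - 4 * (lon + sign * ha) - st$eqtime
  as.POSIXct(as.numeric(as.POSIXct(paste(format(date), "00:00:00"),
                                   tz = "UTC")) + minutes * 60,
             tz = "UTC", origin = "1970-01-01")
}

#' Day length at a site for a sun elevation threshold
#'
#' @inheritParams twilight_time
#' @return Day length in hours; `NA` under polar day/night at the threshold.
#' @export
day_length <- function(date, lat, lon = 0, angle = 0) {
  sr <- twilight_time(date, lat, lon, angle, rise = TRUE)
  ss <- twilight_time(date, lat, lon, angle, rise = FALSE)
  as.numeric(difftime(ss, sr, units = "hours"))
}
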