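# Independent oracles used across the suite. These re-derive expected values
# by brute force or closed form, independently of the implementation paths
# they check.

# exhaustive two-sided permutation p using |mean(a) - mean(b)| as statistic
perm_oracle_p <- function(a, b) {
  x <- c(a, b)
  n <- length(x); na <- length(a)
  obs <- abs(mean(a) - mean(b))
  idx <- utils::combn(n, na)
  stats <- apply(idx, 2, function(ii)
    abs(mean(x[ii]) - mean(x[-ii])))
  mean(stats >= obs - 1e-12)
}

# haversine distance from first principles (Earth radius 6371 km)
haversine_oracle <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r; dlon <- (lon2 - lon1) * r
  a <- sin(dlat / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon / 2)^2
  2 * 6371 * asin(sqrt(pmin(1, a)))
}

# brute-force minimum-elevation profile: densify each leg with geosphere's
# own great-circle interpolation at a much finer step, bin by latitude
dense_profile_oracle <- function(track, dem, bin_deg = 0.1, n_per_leg = 2000) {
  pts <- list()
  for (i in seq_len(nrow(track) - 1)) {
    gc <- geosphere::gcIntermediate(c(track$lon[i], track$lat[i]),
                                    c(track$lon[i + 1], track$lat[i + 1]),
                                    n = n_per_leg, addStartEnd = TRUE)
    pts[[i]] <- data.frame(lon = gc[, 1], lat = gc[, 2])
  }
  pts <- do.call(rbind, pts)
  elev <- dem_elevation(dem, pts$lat, pts$lon)
  bin <- floor(pts$lat / bin_deg) * bin_deg
  agg <- tapply(elev, bin, min)
  data.frame(lat_bin = as.numeric(names(agg)), min_masl = as.numeric(agg))
}

# UTC instant for a Singapore Time (UTC+8) date-time string
sgt_instant <- function(s) as.POSIXct(s, tz = "UTC") - 8 * 3600
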