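# Shared simulation fixtures, all built in code.

# plan for a tag sitting at one site (the second waypoint is a nominal
# 11 m offset so the plan has a leg; the bird never flies during the stay)
stationary_plan <- function(lat = 45, lon = 10, days = 30,
                            start = "2019-01-05", seed = 7, ...) {
  simulation_plan(data.frame(lat = c(lat, lat + 1e-4), lon = c(lon, lon)),
                  stopover_days = c(days, 0),
                  start_time = as.POSIXct(start, tz = "UTC"),
                  seed = seed, ...)
}

# random northward migration with k planted stopovers of known duration;
# returns the plan plus the true per-stopover arrival/departure windows
random_migration <- function(seed, stop_days = NULL) {
  set.seed(seed)
  k <- sample(1:3, 1)
  durs <- if (is.null(stop_days)) stats::runif(k, 3, 20) else
    rep_len(stop_days, k)
  wlat <- 1.45; wlon <- 103.73
  for (i in seq_len(k + 1)) {
    wlat <- c(wlat, wlat[length(wlat)] + stats::runif(1, 4, 8))
    wlon <- c(wlon, wlon[length(wlon)] + stats::runif(1, -2, 2))
  }
  plan <- simulation_plan(data.frame(lat = wlat, lon = wlon),
                          stopover_days = c(6, durs, 30), seed = seed)
  list(plan = plan, k = k, durs = durs)
}

# true residency interval of a plan waypoint, read off the truth track
truth_site_interval <- function(truth, site_idx) {
  ph <- sprintf("site%02d", site_idx)
  tt <- as.numeric(truth$time[truth$phase == ph])
  c(arrival = min(tt), departure = max(tt))
}
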