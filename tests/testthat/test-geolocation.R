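# A 30-day stationary mid-winter deployment used by several blocks.
.winter <- local({
  plan <- stationary_plan(45, 10, days = 30, start = "2019-01-05", seed = 7)
  truth <- simulate_track(plan)
  light0 <- simulate_light(truth, plan, shading = FALSE)
  light <- simulate_light(truth, plan, shading = TRUE)
  list(plan = plan, truth = truth, light0 = light0, light = light)
})

test_that("twilight detection is monotone-invariant and flags dark gaps", {
  tw <- detect_twilights(.winter$light0)
  expect_true(all(diff(tw$rise) != 0))  # alternating after cleaning
  # scaling light by 10 with a matching threshold offset moves nothing
  scaled <- .winter$light0
  scaled$light <- scaled$light * 10
  tw10 <- detect_twilights(scaled, threshold = 1 + log(10))
  expect_equal(as.numeric(tw$time), as.numeric(tw10$time), tolerance = 1e-9)
  # constant darkness: no events, gap flag
  dark <- data.frame(time = .winter$light0$time[1] + 300 * (0:1000),
                     light = 1e-4)
  twd <- detect_twilights(dark)
  expect_identical(nrow(twd), 0L)
  expect_true(attr(twd, "gap"))
})

test_that("calibration recovers the sun angle and the shading gamma", {
  tw0 <- detect_twilights(.winter$light0)
  cal0 <- calibrate_twilights(tw0, 45, 10)
  expect_lt(abs(cal0$sun_angle - .winter$plan$sun_angle), 0.2)
  # gamma(2, 0.5) shading: shape recovered within 50%
  plan_l <- stationary_plan(45, 10, days = 100, seed = 21)
  tr_l <- simulate_track(plan_l)
  tw_l <- detect_twilights(simulate_light(tr_l, plan_l))
  cal_l <- calibrate_twilights(tw_l, 45, 10)
  expect_gt(cal_l$shape, 2 * 0.5)
  expect_lt(cal_l$shape, 2 * 1.5)
  # degenerate zero-residual input is flagged, not an error
  expect_true(calibrate_twilights(tw0, 45, 10)$degenerate ||
                sd(cal0$delays) < 1)  # noiseless residuals are ~interp error
  # too little data refuses
  expect_error(calibrate_twilights(tw0[1:6, ], 45, 10), "10 twilight pairs")
})

test_that("threshold positions invert noiseless light at a known site", {
  tw0 <- detect_twilights(.winter$light0)
  cal0 <- calibrate_twilights(tw0, 45, 10)
  path <- threshold_location(tw0, cal0)
  expect_lt(median(abs(path$lon - 10)), 0.5)
  expect_lt(median(abs(path$lat - 45), na.rm = TRUE), 1)
  # translating both twilights +1 h shifts longitude by -15 degrees
  shifted <- tw0
  shifted$time <- shifted$time + 3600
  path_s <- threshold_location(shifted, cal0)
  expect_equal(median(path_s$lon), median(path$lon) - 15, tolerance = 0.1)
  expect_equal(median(path_s$lat, na.rm = TRUE),
               median(path$lat, na.rm = TRUE), tolerance = 1.5)
})

test_that("equinox day lengths leave latitude flagged but longitude usable", {
  plan <- stationary_plan(35, 50, days = 6, start = "2019-03-18", seed = 31)
  tr <- simulate_track(plan)
  tw <- detect_twilights(simulate_light(tr, plan, shading = FALSE))
  path <- threshold_location(tw, plan$sun_angle)
  expect_true(all(path$lat_flagged))
  expect_lt(median(abs(path$lon - 50)), 0.5)
})

test_that("latitude error degrades towards the equinox, longitude does not", {
  errs <- list()
  for (start in c("2019-01-05", "2019-02-05", "2019-03-05")) {
    plan <- stationary_plan(45, 10, days = 12, start = start, seed = 13)
    tr <- simulate_track(plan)
    tw <- detect_twilights(simulate_light(tr, plan, shading = TRUE))
    path <- threshold_location(tw, plan$sun_angle)
    errs[[start]] <- c(lat = median(abs(path$lat - 45), na.rm = TRUE),
                       lon = median(abs(path$lon - 10)))
  }
  lat_err <- vapply(errs, `[[`, numeric(1), "lat")
  lon_err <- vapply(errs, `[[`, numeric(1), "lon")
  expect_true(all(diff(lat_err) > 0))        # monotone seasonal degradation
  expect_lt(max(lon_err), 1)                  # longitude stays equinox-robust
})

test_that("residency grouping finds changepoints and drops 1-day excursions", {
  cal <- calibrate_twilights(detect_twilights(.winter$light), 45, 10)
  # stationary month: a single group
  g <- group_residency(detect_twilights(.winter$light), cal)
  expect_identical(length(setdiff(unique(g$group), NA)), 1L)
  # two 10-day halves 1000 km apart: 2 groups, boundary within a day
  p2 <- geosphere::destPoint(c(10, 45), 90, 1e6, r = 6371000)
  plan2 <- simulation_plan(data.frame(lat = c(45, p2[2]), lon = c(10, p2[1])),
                           stopover_days = c(10, 10),
                           start_time = as.POSIXct("2019-01-01", tz = "UTC"),
                           seed = 17)
  tr2 <- simulate_track(plan2)
  tw2 <- detect_twilights(simulate_light(tr2, plan2))
  g2 <- group_residency(tw2, cal)
  expect_identical(length(setdiff(unique(g2$group), NA)), 2L)
  move_t <- min(tr2$time[grepl("^leg", tr2$phase)])
  last_g1 <- max(g2$time[!is.na(g2$group) & g2$group == 1])
  expect_lt(abs(as.numeric(difftime(last_g1, move_t, units = "days"))), 1)
  # a 1-day excursion is too short to count as residency
  p3 <- geosphere::destPoint(c(10, 45), 90, 1.2e6, r = 6371000)
  plan3 <- simulation_plan(
    data.frame(lat = c(45, p3[2], 45.0001), lon = c(10, p3[1], 10)),
    stopover_days = c(10, 1, 10),
    start_time = as.POSIXct("2019-01-01", tz = "UTC"), seed = 19)
  tr3 <- simulate_track(plan3)
  g3 <- group_residency(detect_twilights(simulate_light(tr3, plan3)), cal)
  expect_identical(length(setdiff(unique(g3$group), NA)), 2L)
})

test_that("MCMC refinement pins endpoints and respects the speed prior", {
  plan <- simulation_plan(data.frame(lat = c(45, 50), lon = c(10, 25)),
                          stopover_days = c(20, 20),
                          start_time = as.POSIXct("2019-01-01", tz = "UTC"),
                          seed = 11)
  tr <- simulate_track(plan)
  tw <- detect_twilights(simulate_light(tr, plan))
  cal <- calibrate_twilights(
    tw[tw$time < as.POSIXct("2019-01-20", tz = "UTC"), ], 45, 10)
  g <- group_residency(tw, cal)
  ref <- refine_track(tw, cal, g, deploy = c(45, 10), fix_last = FALSE,
                      n_init = 300, n_tune = 150, n_final = 600, seed = 2)
  expect_equal(unname(unlist(ref[1, c("lat", "lon")])), c(45, 10))
  # destination group recovered well and inside its credible region
  last <- ref[nrow(ref), ]
  expect_lt(great_circle_km(last$lat, last$lon, 50, 25), 150)
  expect_true(last$lat >= last$lat_lo && last$lat <= last$lat_hi)
  # implied speeds: no implausible jumps at the speed prior's far tail
  sp <- great_circle_km(ref$lat[-nrow(ref)], ref$lon[-nrow(ref)],
                        ref$lat[-1], ref$lon[-1]) /
    as.numeric(diff(as.numeric(ref$time)) / 3600)
  expect_true(all(sp < qgamma(0.999, 2.2, 0.08)))
})

test_that("refinement does not worsen median error on simulated tracks", {
  worse <- 0; n_seed <- 20
  for (s in seq_len(n_seed)) {
    plan <- simulation_plan(data.frame(lat = c(45, 49), lon = c(10, 18)),
                            stopover_days = c(12, 12),
                            start_time = as.POSIXct("2019-01-01", tz = "UTC"),
                            seed = 100 + s)
    tr <- simulate_track(plan)
    tw <- detect_twilights(simulate_light(tr, plan))
    cal <- calibrate_twilights(
      tw[tw$time < as.POSIXct("2019-01-12", tz = "UTC"), ], 45, 10)
    g <- group_residency(tw, cal)
    raw <- threshold_location(tw, cal)
    ref <- refine_track(tw, cal, g, deploy = c(45, 10), fix_last = FALSE,
                        n_init = 300, n_tune = 150, n_final = 600,
                        seed = s)
    # evaluate both paths at the raw estimate times (same weighting)
    ui <- vapply(as.numeric(raw$time), function(q)
      which.min(abs(as.numeric(ref$time) - q)), integer(1))
    pos <- .interp_track(tr, raw$time)
    err_raw <- median(great_circle_km(raw$lat, raw$lon, pos$lat, pos$lon),
                      na.rm = TRUE)
    err_ref <- median(great_circle_km(ref$lat[ui], ref$lon[ui],
                                      pos$lat, pos$lon), na.rm = TRUE)
    if (err_ref > err_raw) worse <- worse + 1
  }
  expect_lte(worse / n_seed, 0.05)  # 5% violation margin
})
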