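test_that("planted stopovers are recovered; short pauses never reported", {
  out <- random_migration(42)
  truth <- simulate_track(out$plan)
  argos <- degrade_to_argos(truth, out$plan)
  seg <- detect_stopovers(argos)
  expect_identical(nrow(seg$stopovers), out$k)
  for (i in seq_len(out$k)) {
    ti <- truth_site_interval(truth, i + 1)
    j <- which.min(abs(as.numeric(seg$stopovers$arrival) - ti["arrival"]))
    expect_lt(abs(as.numeric(seg$stopovers$arrival[j]) - ti["arrival"]) / 3600,
              58)
    expect_lt(abs(as.numeric(seg$stopovers$departure[j]) - ti["departure"]) /
                3600, 58)
  }
  # a 2-day pause is invisible under the 3-day rule
  out2 <- random_migration(43, stop_days = 2)
  argos2 <- degrade_to_argos(simulate_track(out2$plan), out2$plan)
  expect_identical(nrow(detect_stopovers(argos2)$stopovers), 0L)
})

test_that("nearby pauses within the radius merge into one stopover", {
  # two pauses 100 km apart with < 150 km displacement between them
  p2 <- geosphere::destPoint(c(100, 20), 0, 1e5, r = 6371000)
  plan <- simulation_plan(
    data.frame(lat = c(5, 20, p2[2], 35), lon = c(100, 100, p2[1], 100)),
    stopover_days = c(4, 4, 4, 10), seed = 44)
  argos <- degrade_to_argos(simulate_track(plan), plan)
  seg <- detect_stopovers(argos)
  expect_identical(nrow(seg$stopovers), 1L)
  expect_gt(seg$stopovers$duration_days, 8)
})

test_that("segmentation is invariant to finer resampling and idempotent", {
  out <- random_migration(45)
  truth <- simulate_track(out$plan)
  argos <- degrade_to_argos(truth, out$plan)
  s1 <- detect_stopovers(argos)
  s2 <- detect_stopovers(argos)           # idempotent
  expect_identical(s1, s2)
  # doubling fix density on the same path leaves the count unchanged
  dense <- degrade_to_argos(truth, out$plan, cadence_h = 1, aux_every_h = 3)
  s3 <- detect_stopovers(dense)
  expect_identical(nrow(s3$stopovers), nrow(s1$stopovers))
})

test_that("wetness departure rule finds the last wet hour", {
  t0 <- as.POSIXct("2019-04-01", tz = "UTC")
  w <- data.frame(time = t0 + 3600 * (0:19),
                  wetness = c(3, 7, 2, rep(0, 17)))
  expect_equal(detect_departure_from_wetness(w), t0 + 3 * 3600)
  w0 <- data.frame(time = t0 + 3600 * (0:19), wetness = 0)
  expect_null(detect_departure_from_wetness(w0))
  # simulated departure recovered within an hour
  plan <- simulation_plan(data.frame(lat = c(1.45, 20), lon = c(103.73, 98)),
                          stopover_days = c(3, 5), wet_prob = 0.9, seed = 46)
  truth <- simulate_track(plan)
  wet <- simulate_wetness(truth, plan)
  dep <- detect_departure_from_wetness(wet)
  true_dep <- min(truth$time[grepl("^leg", truth$phase)])
  expect_lt(abs(as.numeric(difftime(dep, true_dep, units = "hours"))), 1.5)
})

test_that("seasonal phases cover the track and flag partial migrants", {
  cfg <- pipeline_config()
  bird <- cfg$birds[[1]]
  wp_out <- data.frame(lat = bird$out$lat, lon = bird$out$lon)
  wp <- rbind(wp_out, wp_out[rev(seq_len(nrow(wp_out) - 1)), ])
  plan <- simulation_plan(wp, stopover_days = c(bird$stop_days, 0, 0, 10),
                          start_time = as.POSIXct("2019-04-20", tz = "UTC"),
                          seed = 47)
  argos <- degrade_to_argos(simulate_track(plan), plan)
  seg <- detect_stopovers(argos)
  ph <- assign_phases(argos, seg, breeding_lat = 30)
  expect_false(ph$partial)
  expect_identical(ph$phases$phase[1:4],
                   c("nonbreeding", "northward", "breeding", "southward"))
  # non-overlapping, ordered, covering every fix
  expect_true(all(diff(as.numeric(ph$phases$start)) > 0))
  expect_true(all(ph$phases$end >= ph$phases$start))
  expect_true(all(argos$time >= min(ph$phases$start) &
                    argos$time <= max(ph$phases$end)))
  # a bird that turns back mid-route is a partial migrant
  wp_p <- data.frame(lat = c(1.45, 17, 1.45001), lon = c(103.73, 96, 103.73))
  plan_p <- simulation_plan(wp_p, stopover_days = c(5, 8, 20), seed = 48)
  argos_p <- degrade_to_argos(simulate_track(plan_p), plan_p)
  ph_p <- assign_phases(argos_p, detect_stopovers(argos_p), breeding_lat = 30)
  expect_true(ph_p$partial)
  expect_false("breeding" %in% ph_p$phases$phase)
})

test_that("stopover days plus travel days account for the whole migration", {
  out <- random_migration(49)
  truth <- simulate_track(out$plan)
  argos <- degrade_to_argos(truth, out$plan)
  seg <- detect_stopovers(argos)
  ph <- assign_phases(argos, seg, breeding_lat = 9)
  north <- ph$phases[ph$phases$phase == "northward", ]
  sm <- summarise_migration(argos, seg$stopovers, north$start, north$end)
  expect_gte(sm$days_travelling, sm$days_at_stopovers)
  # whole-day accounting on the SGT calendar, recomputed independently
  expect_identical(sm$days_travelling,
                   as.numeric(as.Date(north$end + 8 * 3600) -
                                as.Date(north$start + 8 * 3600)))
  in_phase <- seg$stopovers[seg$stopovers$arrival >= north$start &
                              seg$stopovers$departure <= north$end, ]
  expect_identical(sm$n_stopovers, nrow(in_phase))
  expect_identical(sm$days_at_stopovers,
                   sum(as.numeric(as.Date(in_phase$departure + 8 * 3600) -
                                    as.Date(in_phase$arrival + 8 * 3600))))
})

test_that("barrier crossings report entry/exit longitudes and direction", {
  dem <- make_dem(passes = data.frame(lon = 92, floor = 4720, width = 0.3))
  # trans-ridge round trip crossing near 92E
  plan <- simulation_plan(data.frame(lat = c(20, 33, 20), lon = c(95, 91, 95)),
                          stopover_days = c(2, 5, 2), seed = 50)
  argos <- degrade_to_argos(simulate_track(plan), plan)
  bc <- detect_barrier_crossing(argos, dem)
  expect_identical(bc$direction, c("north", "south"))
  for (k in 1:2) {
    expect_lt(min(bc$lon_entry[k], bc$lon_exit[k]), 92.5)
    expect_gt(max(bc$lon_entry[k], bc$lon_exit[k]), 91)
  }
  # a coastal (eastern) route never intersects the mask
  plan_e <- simulation_plan(data.frame(lat = c(20, 36), lon = c(100, 100)),
                            stopover_days = c(2, 5), seed = 51)
  argos_e <- degrade_to_argos(simulate_track(plan_e), plan_e)
  expect_identical(nrow(detect_barrier_crossing(argos_e, dem)), 0L)
})
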