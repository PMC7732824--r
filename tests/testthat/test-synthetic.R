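test_that("simulated flight time and stopover residency follow the plan", {
  # 1100 km at 55 km/h with no stopovers: 20 h of flight
  p2 <- geosphere::destPoint(c(103.73, 1.45), 0, 1100 * 1000, r = 6371000)
  plan <- simulation_plan(data.frame(lat = c(1.45, p2[2]),
                                     lon = c(103.73, p2[1])),
                          flight_speed_kmh = 55, seed = 1)
  tr <- simulate_track(plan)
  elapsed <- as.numeric(difftime(max(tr$time), min(tr$time), units = "hours"))
  expect_lt(abs(elapsed - 20), 1.01)  # hourly sampling truncation
  # a 5-day stopover keeps the bird within 1 km of the waypoint
  plan2 <- simulation_plan(data.frame(lat = c(10, 20), lon = c(100, 100)),
                           stopover_days = c(5, 0), seed = 2)
  tr2 <- simulate_track(plan2)
  site <- tr2[tr2$phase == "site01", ]
  expect_gte(as.numeric(difftime(max(site$time), min(site$time),
                                 units = "days")), 5 - 1 / 24)
  expect_true(all(great_circle_km(site$lat, site$lon, 10, 100) < 1))
})

test_that("generators are deterministic under a fixed seed", {
  mk <- function() {
    plan <- random_migration(5)$plan
    tr <- simulate_track(plan)
    list(tr, degrade_to_argos(tr, plan), simulate_light(tr[1:72, ], plan),
         simulate_temperature(tr[1:72, ], plan), simulate_wetness(tr, plan))
  }
  expect_identical(mk(), mk())
})

test_that("truth track length equals the sum of great-circle legs", {
  out <- random_migration(3)
  tr <- simulate_track(out$plan)
  flight <- tr[grepl("^leg", tr$phase), ]
  n <- nrow(flight)
  total <- sum(great_circle_km(flight$lat[-n], flight$lon[-n],
                               flight$lat[-1], flight$lon[-1]))
  wp <- out$plan$waypoints
  legs <- sum(great_circle_km(wp$lat[-nrow(wp)], wp$lon[-nrow(wp)],
                              wp$lat[-1], wp$lon[-1]))
  expect_lt(abs(total - legs) / legs, 0.002)  # within-site hops excluded
})

test_that("argos degradation respects duty cycle and class error bounds", {
  plan <- stationary_plan(days = 58 / 24 + 0.1, seed = 4)
  tr <- simulate_track(plan)
  ar <- degrade_to_argos(tr, plan, aux_every_h = NULL)
  hrs <- as.numeric(difftime(ar$time, tr$time[1], units = "hours"))
  expect_true(all(duty_cycle_on(hrs)))
  # over 58 h exactly two on-windows are sampled
  expect_identical(length(unique(floor(hrs / 58))), 2L)

  # displacement never exceeds the class radius
  plan2 <- random_migration(6)$plan
  tr2 <- simulate_track(plan2)
  ar2 <- degrade_to_argos(tr2, plan2)
  truth_at <- tr2[match(ar2$time, tr2$time), ]
  d <- great_circle_km(ar2$lat, ar2$lon, truth_at$lat, truth_at$lon)
  expect_true(all(d <= ar2$error_km + 1e-6))

  # G3-only vs G1-only: same seed, larger mean displacement for G1
  d_for <- function(mix) {
    a <- degrade_to_argos(tr2, plan2, class_mix = mix, aux_every_h = NULL)
    t_at <- tr2[match(a$time, tr2$time), ]
    mean(great_circle_km(a$lat, a$lon, t_at$lat, t_at$lon))
  }
  expect_gt(d_for(c(G3 = 0, G2 = 0, G1 = 1, LOW = 0)),
            d_for(c(G3 = 1, G2 = 0, G1 = 0, LOW = 0)))
})

test_that("simulated light tracks solar geometry", {
  # equinox at the deployment site: ~12 h between threshold crossings
  plan <- stationary_plan(1.45, 103.73, days = 6, start = "2019-03-18",
                          seed = 8)
  tr <- simulate_track(plan)
  li <- simulate_light(tr, plan, shading = FALSE)
  tw <- detect_twilights(li)
  r1 <- which(tw$rise)[1]            # first rise, paired with the next set
  dl <- as.numeric(difftime(tw$time[r1 + 1], tw$time[r1], units = "hours"))
  expect_lt(abs(dl - 12), 0.5)
  # zero-shading crossings match the solar oracle within half a sample step
  pred <- twilight_time(as.Date(tw$time[1] + 103.73 / 15 * 3600), 1.45, 103.73,
                        plan$sun_angle, rise = tw$rise[1])
  expect_lt(abs(as.numeric(difftime(tw$time[1], pred, units = "mins"))), 2.5)
  # astronomical night sits on the sensor dark floor
  night <- solar_position(li$time, 1.45, 103.73)$elevation < -18
  expect_true(all(li$light[night] < 0.01))
})

test_that("temperature reflects the lapse rate and wetness stops in flight", {
  plan <- simulation_plan(data.frame(lat = c(5, 15), lon = c(100, 100)),
                          stopover_days = c(2, 2), flight_altitude = 4000,
                          seed = 9)
  tr <- simulate_track(plan)
  te <- simulate_temperature(tr, plan, noise_sd = 0)
  fly <- .interp_track(tr, te$time + 2 * 3600)$flying
  # ~26 C colder at 4000 m than at the sea-level site
  expect_lt(abs((mean(te$temperature[!fly]) - mean(te$temperature[fly])) - 26),
            2)
  we <- simulate_wetness(tr, plan)
  hour_fly <- .interp_track(tr, we$time + 1800)$flying
  expect_true(all(we$wetness[hour_fly] == 0))
  expect_true(all(we$wetness >= 0 & we$wetness <= 14))
  # immersion probability 1 hits the cap when stationary
  plan1 <- simulation_plan(data.frame(lat = c(5, 15), lon = c(100, 100)),
                           stopover_days = c(2, 0), wet_prob = 1, seed = 9)
  tr1 <- simulate_track(plan1)
  we1 <- simulate_wetness(tr1, plan1)
  still <- !.interp_track(tr1, we1$time + 1800)$flying
  expect_true(all(we1$wetness[still] == 14))
})

test_that("synthetic DEM has the requested ridge, passes and plains", {
  dem <- make_dem(passes = data.frame(lon = 92, floor = 4720, width = 0.3))
  expect_gte(dem_elevation(dem, 28.5, 90), 5000)
  expect_lt(dem_elevation(dem, 5, 100), 500)
  expect_lt(dem_elevation(dem, 28.5, 92), dem_elevation(dem, 28.5, 90))
  expect_error(make_dem(res = 0), "resolution")
})

test_that("constant wind fields sample back exactly", {
  wf <- make_wind_field(mean_uv = list(surface = c(30, 0), mb850 = c(30, 0),
                                       mb700 = c(30, 0)), perturb_sd = 0)
  w <- wind_at(wf, c(10, 25, 40), c(70, 90, 110),
               as.POSIXct("2019-01-01 02:00", tz = "UTC"), "mb700")
  expect_equal(w$u, c(30, 30, 30))
  expect_equal(w$v, c(0, 0, 0))
  expect_true(is.na(wind_at(wf, 50, 90, wf$times[1], "surface")$u))
})
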