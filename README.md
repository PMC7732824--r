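# flytrack

Migration-track analysis for tagged shorebirds: light-level geolocation,
stopover segmentation, migration metrics, wind and elevation annotation,
and permutation statistics — with a seeded synthetic-data module that
generates every sensor product the chain consumes, so the whole pipeline
runs and validates without any external download.

The package is built for the kind of study that tracks shorebirds (e.g.
Common Redshank, Whimbrel) from equatorial non-breeding grounds to
high-latitude breeding grounds with two tag families:

* **archival light-level geolocators** — positions are inferred by the
  *threshold method*: sunrise/sunset times from a light threshold give
  longitude (from local solar noon) and latitude (from day length at a
  calibrated sun elevation angle), then a Markov chain Monte Carlo
  refinement combines a gamma model of twilight shading error with a
  gamma flight-speed prior (shape 2.2, rate 0.08 on km/h) over residency
  groups, with deployment-site endpoints fixed;
* **Argos satellite transmitters** on a 10 h on / 48 h off duty cycle —
  tracks are segmented into stopovers (≥ 3 days within 150 km of a
  running centroid, flanked by > 150 km movements), seasonal phases,
  ground speeds with propagated error (legs < 20 km/h excluded), and
  barrier crossings over a DEM mask.

Annotation adds wind support `v_w · cos(α)` (α the angle between track
bearing and wind) at surface, 850 mb and 700 mb, scalar airspeed
(ground − support), minimum route elevations per 0.1° latitude bin, and
flight altitude inferred from tag temperature drops at a 6.5 °C/km lapse
rate. Group comparisons use Monte-Carlo permutation tests (standardized
linear statistic, 9999 resamplings, exact enumeration on small samples)
and OLS regressions of speed on wind support and support on
route × direction.

## Worked example

```r
library(flytrack)

# a 30-day deployment at a known site, simulated and inverted
plan  <- simulation_plan(data.frame(lat = c(45, 45.0001), lon = c(10, 10)),
                         stopover_days = c(30, 0),
                         start_time = as.POSIXct("2019-01-05", tz = "UTC"),
                         seed = 7)
truth <- simulate_track(plan)
light <- simulate_light(truth, plan)          # 5-min light with shading
tw    <- detect_twilights(light)              # threshold 1 on log light
cal   <- calibrate_twilights(tw, 45, 10)
cal
#> <calibration> sun angle -2.99 deg, twilight error ~ gamma(1.50, 0.426) min
path  <- threshold_location(tw, cal)
median(great_circle_km(path$lat, path$lon, 45, 10), na.rm = TRUE)
#> [1] 70.07366
```

The calibrated sun elevation angle sits near the simulation's true
threshold angle (−3.5°) shifted by the typical shading the calibration
absorbs, and the median position error of the raw threshold track is
~70 km — inside the ~150 km working error light-level geolocation is
known for. A full synthetic study (two birds, round trip, stopovers,
wind, ridge DEM, route statistics) runs in one call:

```r
res <- run_pipeline(pipeline_config(), seed = 3, out_dir = "run1")
res$summaries[, c("bird_id", "direction", "depart_sgt", "n_stopovers",
                  "arrive_sgt", "days_travelling")]
#>                 bird_id direction depart_sgt n_stopovers arrive_sgt days_travelling
#> hima1 northward   hima1     north 2019-04-26           1 2019-05-06              10
#> hima1 southward   hima1     south 2019-07-16           0 2019-07-18               2
#> east1 northward   east1     north 2019-04-26           2 2019-05-12              16
#> east1 southward   east1     south 2019-07-21           0 2019-07-24               3
```

Departure and arrival dates are Singapore Time (UTC+8) calendar dates,
the reporting convention for this flyway; `run1/` receives Movebank-style
track CSVs, summary/wind/profile tables and a manifest with seeds and
output hashes. A command-line wrapper is installed at
`inst/scripts/flytrack-pipeline.R`.

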