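---
title: "Methods: from raw tag streams to migration inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw tag streams to migration inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flytrack)
```

flytrack implements the analysis chain used to study shorebird migration
between equatorial non-breeding grounds and high-latitude breeding grounds
with two tag families: archival light-level geolocators (~150 km position
error, no transmission) and duty-cycled Argos satellite transmitters
(sub-km to few-km error, 10 h on / 48 h off). This vignette explains the
models behind each stage, the tunable parameters, and the choices made
where the methods literature leaves the design open.

## Light-level geolocation

### The threshold method

A light logger's raw series is reduced to sunrise and sunset events: the
times log-transformed light crosses a fixed threshold (default 1, so the
raw threshold is *e*), linearly interpolated between the 5-min samples.
For a rise/set pair, longitude follows from the pair midpoint (local solar
noon, via the equation of time) and latitude from day length given the
date and a *sun elevation angle* — the solar elevation that corresponds to
the light threshold for this tag, habitat and typical shading. Solar
geometry uses the standard low-precision (NOAA) ephemeris series, accurate
to about 0.1 degrees — two orders of magnitude below the method's working
error.

### Calibration

The sun elevation angle is fitted at the known deployment site as the
angle minimising the summed absolute differences between predicted and
observed twilight times. Because shading (cloud, vegetation, plumage) can
only darken, it delays dawns and advances dusks; the residual *shading
delays* (minutes) are modelled with a gamma distribution fitted by maximum
likelihood to the min-shifted delays. Two numerical choices matter here:

* the fitted shape is bounded below at 1.5. Unconstrained small-sample
  fits frequently land in the monotone (shape < 1) regime whose mode sits
  at zero; used as a likelihood that pulls every refined location toward
  the sample minimum of the calibration window, a noisy order statistic.
* the model is `delay ~ shift + gamma(shape, rate)` with the shift chosen
  so the model median equals the empirical median. The calibrated angle
  already absorbs the typical shading (a least-absolute-residual fit
  matches the median), so aligning medians — rather than anchoring on the
  sample minimum — keeps the likelihood centred on small calibration
  windows.

With zero-noise input the angle is recovered to well under 0.2 degrees;
with gamma(2, 0.5)-minute shading the gamma shape is recovered within
about 50% at a month of twilights, which is sufficient because only the
error envelope's quantiles are consumed downstream.

### The equinox problem

Near the equinoxes day length is ~12 h at every latitude and latitude is
unidentifiable from day length. Rather than a fixed calendar window, an
estimate's latitude is flagged when the local day-length sensitivity
|d(day length)/d(latitude)| falls below `flag_sens` (default 1.5 min per
degree, which flags roughly the three weeks around each equinox at
mid-latitudes). Longitude is unaffected, which the tests assert as a
seasonal sweep: longitude error stays flat while latitude error grows
monotonically toward the equinox.

### Residency grouping

Stationary birds show twilight-to-twilight changes within the shading
envelope. A twilight's movement probability is the smoothed fraction of
its adjacent same-kind time deviations exceeding twice the calibrated 95%
quantile (a difference of two independent delays); twilights above 0.5
are movement, and residency runs shorter than 2 days are dissolved. The
cited grouping method's exact probability model is not public, so this
explicit rule stands in; it recovers planted changepoints within a day on
simulated two-site data and discards 1-day excursions.

### MCMC refinement

Locations are refined with a Metropolis-within-Gibbs sampler over one
location per residency group and one per movement twilight (two per
movement day). The likelihood is the calibrated gamma delay model
(negative delays, physically impossible, are quadratically penalised with
a 5-minute tolerance); the prior is a relaxed gamma on great-circle ground
speeds between consecutive locations (shape 2.2, rate 0.08 on the km/h
scale, with a small density floor so that stationarity is not excluded).
Two details are load-bearing:

* speed-prior time gaps run between adjacent *boundary* twilights of the
  location units, not their mean times — a residency's centre is days
  away from its edges, and using centre-to-centre gaps would make the
  speed prior prefer locations thousands of kilometres apart;
* the first (and, when the logger records at the deployment site again,
  the last) location is fixed to the deployment site.

The schedule follows the tune-then-run convention: an initialisation run
(default 1000 iterations), three tuning runs (300 each) adapting the
per-location random-walk scale to 20–40% acceptance, then 2000 final
iterations from which medians and 2.5/97.5% quantiles are reported, with
a split-chain scale-reduction warning above 1.2. The test suite uses
shorter schedules (300/150/600) on small simulations; these converge on
the few-unit problems tested while keeping the suite fast.

## Stopover segmentation

A stopover is a maximal run of fixes within 150 km of the running
centroid (robust to within-site drift), lasting at least 3 days, flanked
by movements beyond 150 km. Because the transmitters are duty cycled, the
3-day test is applied to the *outer bracket* of a candidate residency —
from the last distant fix before arrival to the first distant fix after
departure — which can never under-cover the true residency; a planted
3-day stopover is therefore always retained, while a 2-day pause can
never satisfy the rule (its outer bracket stays under 3 days given the
tag model's fix gaps). Reported arrival and departure are the midpoints
of the bracketing fix gaps. Stopovers shorter than 3 days are not
searched for at all: the duty cycle makes them undetectable in the worst
phase, so reporting them would be false precision.

Seasonal phases follow from residencies: the one containing deployment is
non-breeding; the northernmost at or above the breeding latitude
(default 30 N for plateau breeders, 60 N for Russian breeders) is
breeding; the gaps between are the migrations. Tracks with no residency
at breeding latitudes are flagged partial migrants (sub-adult behaviour)
and excluded from adult summaries.

## Metrics

Distances are spherical great circles at Earth radius 6371.0 km
(an ellipsoidal Earth changes nothing at the tags' error scale and the
wording of the distance definition is explicitly spherical). Migration
distance sums legs through retained fixes and stopover centroids within
the phase, optionally anchored at the terminal residency centroids so
duty-cycle gaps at the phase edges do not drop distance — a *minimum*
flight distance. Ground speed per leg is distance over elapsed time with
error (r1 + r2)/dt; legs under 20 km/h are excluded (slow apparent speeds
can hide undetected stopovers), and legs longer than 24 h are not formed
at all since they span the off period. Whole-day durations are calendar
date differences in Singapore Time (UTC+8), the study's reporting
convention; this reproduces the printed trans-Himalayan day counts from
their date pairs.

## Environmental annotation

Wind support is v_w cos(alpha) with alpha the angle between the leg's
initial great-circle bearing and the wind direction, sampled at the leg
midpoint in space and nearest time (the annotation convention of the
standard track-annotation services, bilinear in space). Airspeed is the
scalar ground speed minus support; the crosswind component is ignored
because the downstream regressions use scalar airspeed, and a
vector-subtraction option (`vector_airspeed`) is provided — the two agree
exactly when crosswind is zero. The "maximum" level is the pointwise
maximum of the three signed supports. Minimum-elevation profiles densify
the route to 0.01-degree steps, sample the DEM bilinearly, and take the
minimum per half-open 0.1-degree latitude bin; the per-individual summary
is the equal-weight mean over bins (the route-length-weighted alternative
was considered and rejected as it double-counts slow coastal sections).
Altitude from tag temperature is deltaT / 6.5 C per km, with deltaT
measured against the mean of the last 24 h before the wetness-derived
departure (the end of the last hour with wetness > 0 before a sustained
12-h dry run).

## Statistics

The two-sample comparison is a Monte-Carlo permutation test with the
standardized linear statistic: T = sum of group A, Z = (T − E[T]) /
sqrt(Var[T]) with moments exact under the permutation null, and a
two-sided p as the proportion of resampled |Z*| at or above |Z| over 9999
resamplings. When the number of distinct arrangements is at most 20 000
the null is enumerated exhaustively instead. The Monte-Carlo p uses the
raw proportion floored at 1/n_resamples; the +1 finite-sample correction
is deliberately not applied (switchable), matching the reporting style of
the permutation framework mirrored here. Regressions (speed on support;
support on route x direction with eastern/northward reference levels;
north on south durations) are ordinary least squares via `lm`, reporting
F, df, p, R-squared and coefficient ± SE; repeated measures are treated
as independent, as in the study design this mirrors.

## The synthetic-data module

The generators define the study conditions the pipeline is validated
under: great-circle migration legs at 55 km/h and 4000 masl between
waypoints; 10 h on / 48 h off duty cycling with Argos class errors drawn
uniformly within the class radius (G3 0.25, G2 0.5, G1 1.5, LOW 5 km) and
sparse 6-hourly LOW fixes outside the schedule, emulating solar tags that
transmit when fully charged; light as a saturating logistic of solar
elevation with a dark floor and one-sided gamma(2, 0.5)-minute shading
(delaying dawns, advancing dusks); temperature as a latitudinal surface
climatology minus 6.5 C per km of true altitude in 4-h blocks; hourly
wetness counts in 0–14, always zero in flight; a Himalaya-like ridge DEM
(crest 5500 masl across 27–30 N, 75–97 E, with insertable low passes) and
smooth mean-plus-sinusoid wind fields at three pressure levels. Truth
tracks are generated at 1-h cadence with exact leg endpoints so path
length is conserved, and 0.3-km within-site jitter, far below the 150-km
segmentation radius.

What the generator does *not* emulate — and hence what green tests do not
show about real data: wind-responsive flight (simulated ground speed is
constant, so the speed-on-support slope in pipeline output is ~0 and the
airspeed slope ~−1, the controlled algebraic limit; slope *recovery* is
instead tested on synthetic regressions with a planted slope), twilight
outliers beyond the gamma model, Argos error's heavy tails and
location-class misreporting, orographic winds, sea-surface temperature,
and fuel-load physiology.

## Problem sizes and runtime choices

Tests run stationary calibrations of 12–100 days, two-site refinements
with shortened MCMC schedules, 20-seed segmentation and refinement
sweeps, 1000-replicate type-I calibration at 9999 resamples, and
200-point regression recoveries. These sizes were chosen so each property
is measured with comfortable statistical margin while the full suite
stays fast enough to run routinely.

## Known limitations

* Calibration transfers the deployment-site sun angle to all latitudes;
  real habitat shifts between sites bias latitude, as with any threshold
  geolocation.
* The movement-probability rule is a documented stand-in for the cited
  grouping method, not a reimplementation of it.
* Near-equinox latitude from the refinement remains weakly identified;
  the credible intervals express this but the paired raw-vs-refined error
  comparison is only asserted away from the equinoxes.
* The wind file format is a long-format CSV grid rather than NetCDF; the
  reader's schema is documented so real reanalysis exports can be
  converted trivially.
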