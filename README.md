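# arurhythm

Tools for turning automated radio-telemetry (ARU) signal logs of
free-living songbirds into circadian activity analyses: threshold
calibration, per-minute activity classification, nocturnal departure
detection, civil-twilight computation, 30-minute activity budgets, and
penalized-spline binomial GAMMs plus REML linear mixed models for comparing
the daily rhythms of migrant and resident phenotypes in a partially
migratory population.

## The problem

A radio tag on a bird is re-scanned by fixed receivers once per minute,
logging signal and noise strength in dBm. When the bird moves, the signal
strength changes; when it is still, the signal is stable. From this, each
tag-minute can be classified as

* **active** — the absolute one-minute change in signal strength |Δ|
  exceeds a calibrated threshold (4.0 dB by default: the 99% upper quantile
  of |Δ| from motionless reference tags deployed for a week),
* **inactive** — |Δ| at or below the threshold, or
* **unknown** — the minute is unusable: no record, signal below a minimum
  (−127.0 dBm: 4 dB above the mean upper 95% quantile of white noise),
  signal-to-noise gap under 10 dB, noise above −130 dBm (area-wide
  electronic noise, e.g. thunderstorms), or no usable record exactly one
  minute earlier.

Days with ≥ 10% unknown minutes are discarded. A migratory **departure**
is the first time stamp after which the signal is permanently absent
(followed only by unknowns, for at least 24 h). Activity is aggregated
into 30-minute budgets — the proportion of known minutes active — labelled
day or night by civil twilight (sun 6° below the horizon), aligned to a
window from 7 days before each departure to local midnight of the
departure night, and each migrant event is randomly paired with a resident
covering the same window.

The inference stage models the probability of being active, per half-hour
bin with `trials = known minutes`, as a logit-link binomial GAMM:
cyclic (or natural) cubic regression spline smooths of time of day (by
migratory status), random intercepts for individual (and year), and an
observation-level random effect against overdispersion. Fitting is
penalized IRLS with Fellner–Schall selection of smoothing parameters and
variance components (a Laplace/PQL-class criterion). Post-hoc stages:
working residuals of the hourly model averaged per bird-day, day and night
separately, fed to REML LMMs `residual ~ days_before_departure × status`;
and a seasonal LMM comparing log night activity in mid-August
(13–20 August) versus the ten pre-departure days.

A synthetic ARU generator with known ground truth (diurnal Bernoulli
activity, per-receiver signal baselines, movement jumps, bursty dropouts,
noise storms, static calibration tags, night-time departures drawn
0.1–4.7 h after civil dusk and before midnight) makes the whole chain
testable without field data.

## Worked example

```r
library(arurhythm)

cfg <- sim_config(n_migrants = 3, n_residents = 3, n_departure_events = 3,
                  start_date = "2015-09-20", end_date = "2015-10-10",
                  departure_date_range = c("2015-09-29", "2015-10-07"),
                  seed = 5)
report <- run_pipeline(cfg = cfg)
report
#> <pipeline_report>
#>   seasons: 6 | departures detected: 3 | pairs: 3
#>   thresholds: activity 4 dB, min signal -133.7 dBm
#>   daily GAMM status effect: -0.0156 +/- 0.0634 (z = -0.25, p = 0.806)
#>   note: PQL-class penalized fits; known-minute denominator
```

The calibrated activity threshold recovers the 4.0 dB generative value
from the simulated static tags (the simulated noise floor is quieter than
the field site's, hence the lower minimum-signal threshold). All three
simulated departures are detected, each is paired with a resident, and the
daily GAMM finds no day/night activity difference between the phenotypes —
the expected behaviour under the generator's default abrupt-switch
scenario, where migrants keep resident-like rhythms until the night of
departure:

```r
report$summary_day_night
#> # A tibble: 4 × 5
#>   daynight mean_pct sd_pct n_bird_days status
#>   <chr>       <dbl>  <dbl>       <int> <chr>
#> 1 day         26.2    1.71          18 migrant
#> 2 night        3.49   1.16          21 migrant
#> 3 day         25.9    1.63          17 resident
#> 4 night        3.42   1.23          19 resident
```

(Classified percentages sit a few points below the generative daytime rate
because not every true movement produces a threshold-crossing signal
change; see the methods vignette.)

Individual stages are exported: `read_aru_log()`, `collapse_receivers()`,
`calibrate_thresholds()`, `classify_series()`, `daily_quality()`,
`detect_departure()`, `civil_twilight()`, `activity_budget()`,
`align_to_departure()`, `pair_resident()`, `fit_binomial_gam()`,
`fit_lmm()`, `render_actogram()` (double-plotted 48-h actograms),
`plot_aligned_means()`.

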