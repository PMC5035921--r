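---
title: "From receiver logs to circadian inference: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From receiver logs to circadian inference: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arurhythm)
```

This vignette documents the models and procedures implemented in
`arurhythm`, the assumptions behind them, and the choices made where the
underlying field protocol left the design open.

## 1. Signal model and classification

An automated receiving unit (ARU) scans each tag frequency once every 60
seconds and logs signal and noise strength (dBm). The behavioural signal
is the *change* in signal strength between successive one-minute
recordings: a moving bird changes the orientation and position of its tag
antenna, a still bird does not.

**Delta is unsigned.** The activity rule thresholds the change in signal
strength; only the magnitude |Δ| is physically meaningful for movement, so
pooled calibration deltas and the classification rule both use absolute
differences.

**Threshold calibration.** Motionless reference tags deployed across the
site for a week define the null distribution of |Δ|; its upper 99%
quantile (linear interpolation between order statistics, the "type 7"
convention — fixed because reproducibility requires committing to one, and
configurable) is the activity threshold. The shipped default is 4.0 dB.
The minimum-signal threshold is the mean, over receiver-day groups, of the
95% quantile of recorded noise, plus a 4 dB margin (default −127.0 dBm).
The grouping behind "the noise recorded at the same time" is not uniquely
determined by the protocol; receiver-days are used because noise floors
differ by receiver and drift by day, and the choice is documented and
isolated in `group_noise_by_receiver_day()`.

**Rule order.** Unknown rules run before the activity rule: a minute with
no record, signal under the minimum, signal-to-noise gap under 10 dB, or
noise above −130 dBm is unknown regardless of Δ, as is a minute whose
*previous* minute is missing or unusable (Δ is defined only between
successive one-minute recordings — a two-minute difference is not
inherited). A change exactly at the threshold classifies as inactive
("above" is strict). Raising the threshold can therefore only reduce
active counts, and relaxing any unknown rule can only reduce unknowns —
both properties are tested.

**Receiver fusion.** With three to five receivers hearing the same tag,
the strongest-signal record per tag-minute is kept before classification.
This maximises detection probability and is deterministic; the field
protocol does not state how overlapping detections were merged, so this is
a package design choice, not a reproduction. Its known artifact: when the
strongest receiver changes between two successive minutes, baseline
differences between receivers can masquerade as movement. With bursty
(rather than minute-wise independent) dropouts such switches are rare;
residual false actives of a few percent remain and are visible in the
worked examples.

**Quality filter.** Days (local calendar days, midnight to midnight at the
site offset) with unknown fraction ≥ 0.10 are unusable — the inequality is
strict ("under 10%"). Whether the field "day" was calendar or dawn-to-dawn
is unstated; calendar days are used and the boundary convention is tested.

**Departure detection.** The departure instant is the start of the
terminal run of unknown states — the first time stamp after which the
signal is permanently absent. The terminal run must last at least
`min_absence_hours` (default 24 h); without this guard, any dropout
touching the end of the data window would be called a departure, and the
field protocol's visual confirmation step is replaced by this tunable plus
a `confirmed = FALSE` flag for human review. Absence that ends (signal
reappears) is unknown time, never a departure. A noise storm immediately
preceding a true departure extends the terminal unknown run backwards and
shifts the detected time early — exactly the artifact class the manual
confirmation step existed for.

## 2. Solar geometry

Civil dawn and dusk are the crossings of geometric solar altitude through
−6°, computed from a NOAA/Meeus-class low-precision ephemeris (geometric
mean longitude, equation of centre, apparent longitude, corrected
obliquity, equation of time; declination accurate to ≲0.01°). No
refraction term is applied: civil twilight is defined geometrically.
Crossings are bracketed on a one-minute grid and bisected to under one
second. Polar day/night produce an explicit "no twilight" result. Daytime
is `[dawn, dusk)`; all other minutes belong to the night beginning at the
most recent dusk.

Tests compare against an independently coded Fourier-series ephemeris
(Spencer's truncated-series declination and equation of time). That oracle
itself carries up to ~0.3° from series truncation and leap-year phase, so
altitude agreement is asserted at 0.35° and twilight times at ±5 minutes
over latitudes −35° to 47.8°; poleward of ~60° the −6° crossing becomes so
shallow near the polar-day boundary that minute-level comparison of two
low-precision algorithms stops being meaningful.

## 3. Budgets, alignment, pairing

Activity budgets are clock-aligned half-open 30-minute bins carrying
counts of active/inactive/unknown minutes (always summing to 30), a
day/night label taken at the bin midpoint (bins straddling twilight are
not split), and the proportion of **known** minutes active. The
known-minute denominator is the default because the separate <10%
uncertainty filter already bounds the unknown share; counting unknowns as
inactive would bias activity down precisely on the poorer days. The
total-minute denominator is available via `denominator = "total"`.

Departure alignment keeps bins from 7 days before the departure instant to
local midnight of the departure night, annotates integer local-date
offsets (`days_before_departure`, 0 on the departure day), and drops
quality-failing days. Each migrant event is paired with a uniformly drawn
resident whose data cover the window (residents may repeat across events).
Lumping the window into one 24-h day re-keys bins by local time of day
and keeps the (successes, trials) pair for binomial modelling.

## 4. The mixed-model stage

The probability that a bird is active is modelled per 30-minute bin as a
binomial GAMM with logit link:

* smooth terms: cyclic cubic regression splines of time of day for the
  24-h (hourly) model — value, first- and second-derivative continuity at
  the 0 ≡ 24 h wrap — and a natural cubic regression spline as the 1-D
  default smoother for the daily model. In one dimension the natural
  spline has the same integrated-squared-second-derivative penalty and the
  same `{1, x}` null space as a thin-plate smoother, and practically
  indistinguishable fits; the exact thin-plate eigen-basis is out of
  scope. `by =` factors give one independently smoothed curve (own
  smoothing parameter) per level. Defaults `k = 10`; sum-to-zero
  constraints are absorbed into the basis.
* random intercepts for individual (and year in the hourly model),
  represented as ridge-penalized dummy blocks: variance component σ²
  corresponds to ridge weight 1/σ².
* an observation-level random effect (OLRE) in the daily model absorbing
  extra-binomial variation. Because its penalized block is diagonal, it is
  folded into the working weights by block elimination (a Schur
  complement), so the solved system never grows with n.

Coefficients come from penalized IRLS with step halving (the penalized
deviance is non-increasing across accepted steps, relative-change
convergence at 1e-8, 200-iteration cap, non-convergence is an error
carrying the deviance trace). Smoothing parameters and variance components
are selected by generalized Fellner–Schall updates of the Laplace/PQL-class
marginal criterion, interleaved with IRLS; this is an approximation to
full marginal-likelihood fitting, so small differences from other software
are expected, and fixed parameters can be supplied instead (`lambda =`).
Wald tests use the penalized information matrix: z = estimate/SE with a
two-sided normal p. Curve predictions are population-level (random blocks
at zero), ± 1.96 SE on the link scale and inverse-linked, so intervals
always lie in (0, 1).

The Wald z-test conditions on estimated variance components, which makes
it slightly anticonservative when few individuals carry the between-group
comparison; at the study's design size (21 + 23 individuals) the type-I
error sits near its nominal level, and that is the size at which the
calibration property is tested.

**Residual analyses.** Working residuals `(p̂ − μ)/(μ(1−μ))` of the hourly
GAMM (which has no OLRE — an OLRE would absorb the very residual variation
being examined) are averaged per individual per day before departure,
separately for day and night bins, and modelled by REML LMMs
`residual ~ days_before_departure × status` with individual and year
intercepts. Which residual type the original analysis extracted is
unstated; working residuals are the default and the choice is isolated in
one place. The August comparison models
`log(mean night activity + ε)` with period × status fixed effects;
ε defaults to half the smallest nonzero observable per-bin proportion,
1/60, because the log of exact zeros is otherwise undefined — the original
analysis states only "log transformed".

**REML.** Variance components maximise the restricted likelihood by Fisher
scoring with analytic score and expected information, step halving, and an
active-set guard allowing exact zeros; on balanced one-way designs the
estimates equal the ANOVA expected-mean-square estimators to 1e-8 (tested,
and cross-checked against `lme4`). Fixed-effect t-tests use `df = n − p`,
a deliberately simple residual-df convention.

## 5. The synthetic generator

The generator exists so that every downstream stage can be tested against
known truth. Its defaults are the study conditions: site 47.783°N 9.033°E,
season 10 August – 31 October, daytime per-minute activity probability
0.35 and night 0.02 (the field estimates were ≈37% and ≈2%), 21 migrants
contributing 24 departure events (one individual with two departures in
consecutive years, one with three — extra events shift that bird's season
by whole years), 23 residents, departures on 23 September – 26 October at
civil dusk + U[0.1, 4.7] h, rejection-sampled to stay before local
midnight, 13 static calibration tags for one week, three receivers with
90% availability, and about one area-wide noise storm per week.

Signal structure per receiver: a baseline uniform on [−110, −90] dBm plus
a shared movement offset plus stationary noise scaled so a motionless
tag's one-minute Δ is Normal(0, `sigma_still`). `sigma_still` defaults to
4.0/Φ⁻¹(0.995) ≈ 1.55 dB so that the half-normal 99% quantile — the
calibrated threshold — is exactly the nominal 4.0 dB. On an active minute
the movement offset jumps by at least 4 dB with probability
`p_exceed_active` (default 0.9; the field data give no Δ distribution for
a moving bird, so this is a free parameter), with jump direction forced
inward once the offset strays more than 8 dB from baseline, keeping
signals in reception range without reflection artifacts. Departure is a
1–3 minute take-off burst of |Δ| ≥ 8 dB followed by silence; the truth
table records both take-off start and the instant the tag leaves reception
(burst end), the latter being what the absence-based detector estimates.
Dropouts are bursty (geometric in/out episodes, mean outage 10 min) rather
than independent minutes — a bird drifts out of range for a stretch, not
for isolated seconds — which also keeps strongest-receiver switches, and
their false-active artifacts, at realistic rates.

Activity is minute-wise Bernoulli, not a bout model: the pipeline consumes
only minute states and 30-minute proportions, and no bout statistics were
available to calibrate one. Consequences worth knowing: simulated
between-bird-day variation in percent activity is far smaller than the
±17% SD seen in the field (which reflects behavioural correlation the
generator does not model), so passing tests show the *pipeline* recovers
its inputs, not that real birds behave like the generator. The
optional `zugunruhe_ramp` hook replaces the night probability with a
function of days before departure, emulating the gradual captive-style
onset of migratory restlessness as the alternative scenario.

Per-bird random streams are derived from (master seed, bird id, year), so
adding birds to a configuration never perturbs existing ones, and equal
seeds reproduce byte-identical datasets.

## 6. Problem sizes and numerical settings

Test and acceptance runs use reduced problem sizes chosen to exercise
every code path at desk scale: seasons of 11–18 days around the departure
window, populations of 4–50 birds, `k = 6–10` basis dimensions, 100
end-to-end power replicates and 500 null replicates for test calibration.
The daily model's full status × day smooth interaction (16 smooths) is
supported via `daily_by_day = TRUE`; the default fits one smooth per
status, which is the appropriate reduction at these sizes. Convergence
tolerances: IRLS relative penalized deviance 1e-8 (cap 200); outer
Fellner–Schall log-λ step 5e-3 (cap 40); λ clamped to [1e-7, 1e8]; REML
scoring to score norm 1e-8 with variance floors at zero.

## 7. Known limitations

* The visual artifact screening of the field protocol is replaced by
  automated rules plus review flags; residual discrepancies with manually
  curated data are expected.
* Strongest-signal fusion plus receiver baseline differences produces a
  low rate of false actives at receiver hand-overs; per-receiver Δ
  computation would remove it at the cost of discarding cross-receiver
  minutes.
* PQL-class fitting slightly biases variance components for binomial data
  with small trial counts; with 30-minute bins (≤30 trials) the effect is
  minor but p-values need not match full-Laplace software to the digit.
* `df = n − p` t-tests ignore variance-component uncertainty
  (no Satterthwaite correction).
* A single constant UTC offset defines local time; the end-of-October
  DST transition is ignored, so "local midnight" drifts one hour in the
  season's final days relative to wall-clock time.
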