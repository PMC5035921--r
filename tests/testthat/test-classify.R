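thr <- default_thresholds()

rec1 <- function(sig, noise = -141, t = "2015-10-14 18:00:00") {
  make_records(sig, start = t, noise = noise)
}

test_that("minute classification applies the threshold rules in order", {
  prev <- rec1(-95)
  curr <- rec1(-89, t = "2015-10-14 18:01:00")
  expect_equal(classify_minute(prev, curr, thr), "active")    # delta 6 > 4
  curr0 <- rec1(-95, t = "2015-10-14 18:01:00")
  expect_equal(classify_minute(prev, curr0, thr), "inactive") # delta 0
  # weak signal below -127 dBm
  weak <- rec1(-128, t = "2015-10-14 18:01:00")
  expect_equal(classify_minute(prev, weak, thr), "unknown")
  # signal-to-noise gap under 10 dB
  gap <- rec1(-100, noise = -108, t = "2015-10-14 18:01:00")
  expect_equal(classify_minute(prev, gap, thr), "unknown")
  # noise above the -130 dBm ceiling
  noisy <- rec1(-100, noise = -125, t = "2015-10-14 18:01:00")
  expect_equal(classify_minute(prev, noisy, thr), "unknown")
  # missing current or previous minute
  expect_equal(classify_minute(prev, NULL, thr), "unknown")
  expect_equal(classify_minute(NULL, curr, thr), "unknown")
  # previous not exactly one minute earlier
  far <- rec1(-95, t = "2015-10-14 17:58:00")
  expect_equal(classify_minute(far, curr, thr), "unknown")
  # exactly at the threshold: inactive (strict > for active)
  at <- rec1(-91, t = "2015-10-14 18:01:00")
  expect_equal(classify_minute(prev, at, thr), "inactive")
})

test_that("series classification reproduces the rule pattern over a run", {
  sig <- c(-100, -100, -100, -94, -94, -99, -99, -99, -99, -99)
  ser <- classify_series(make_records(sig), thr)
  expect_equal(ser$states,
               c("unknown", "inactive", "inactive", "active", "inactive",
                 "active", "inactive", "inactive", "inactive", "inactive"))
  # all storm minutes unknown
  storm <- make_records(rep(-95, 10), noise = -125)
  expect_true(all(classify_series(storm, thr)$states == "unknown"))
  # dropout minutes appear as unknown; span is kept gap-free
  gappy <- make_records(c(-100, -100, -100, -100, -100))
  gappy <- gappy[-c(3, 4), ]
  ser2 <- classify_series(gappy, thr)
  expect_equal(length(ser2), 5)
  expect_equal(ser2$states,
               c("unknown", "inactive", "unknown", "unknown", "unknown"))
})

test_that("state partition is complete on fuzzed inputs", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(50:300, 1)
    rec <- make_records(runif(n, -135, -85), noise = runif(n, -145, -124))
    keep <- runif(n) > 0.2
    ser <- classify_series(rec[keep, ], thr)
    tab <- table(factor(ser$states, c("active", "inactive", "unknown")))
    expect_equal(sum(tab), length(ser))
  }
})

test_that("raising the activity threshold never creates active minutes", {
  set.seed(12)
  rec <- make_records(cumsum(rnorm(500, 0, 3)) - 100)
  counts <- vapply(c(2, 4, 6, 10), function(a) {
    t2 <- cal_thresholds(activity_delta_db = a)
    sum(classify_series(rec, t2)$states == "active")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("clean synthetic data is recovered almost perfectly", {
  cfg <- small_cfg(n_receivers = 1, p_detect = 1, p_exceed_active = 1,
                   sigma_still = 0.3, seed = 17)
  m <- bird_meta("R01", "resident", year = 2015)
  sim <- simulate_bird(cfg, m)
  ser <- classify_series(collapse_receivers(sim$records), thr,
                         start = min(sim$truth$timestamp),
                         end = max(sim$truth$timestamp))
  truth <- sim$truth$true_state
  st <- ser$states
  known <- st != "unknown"
  sens <- mean(st[known & truth == "active"] == "active")
  spec <- mean(st[known & truth == "inactive"] == "inactive")
  expect_gte((sens + spec) / 2, 0.95)
})

test_that("daily quality applies the strict 10 percent rule", {
  mk_day <- function(n_unknown) {
    states <- rep("inactive", 1440)
    if (n_unknown > 0) states[seq_len(n_unknown)] <- "unknown"
    activity_series("t", "2015-10-13 22:00:00", states)  # midnight local
  }
  q1 <- daily_quality(mk_day(100), 2)
  expect_equal(q1$unknown_fraction, 100 / 1440, tolerance = 1e-12)
  expect_true(q1$usable)
  # exactly 10% is NOT usable ("under 10%")
  q2 <- daily_quality(mk_day(144), 2)
  expect_equal(q2$unknown_fraction, 0.10)
  expect_false(q2$usable)
  q3 <- daily_quality(mk_day(1440), 2)
  expect_equal(q3$unknown_fraction, 1)
  expect_false(q3$usable)
})

test_that("departure detection finds the terminal absence and ignores dropouts", {
  # constructed truth: known until 21:40 local (19:40 UTC), unknown after
  states <- c(rep("inactive", 1000), rep("unknown", 2000))
  t0 <- as.POSIXct("2015-10-13 03:00:00", tz = "UTC")
  ser <- activity_series("M01", t0, states)
  ev <- detect_departure(ser, min_absence_hours = 24)
  expect_equal(ev$departure_time, t0 + 1000 * 60)
  expect_false(ev$confirmed)
  # a 2-h mid-series dropout that resumes is not a departure
  states2 <- c(rep("inactive", 500), rep("unknown", 120),
               rep("inactive", 2000))
  expect_null(detect_departure(activity_series("R01", t0, states2)))
  # short terminal run below min_absence: no departure either
  states3 <- c(rep("inactive", 3000), rep("unknown", 120))
  expect_null(detect_departure(activity_series("R01", t0, states3)))
  # all unknown: no baseline, warn
  expect_warning(
    expect_null(detect_departure(activity_series("X", t0,
                                                 rep("unknown", 100)))),
    "entirely unknown")
})

test_that("departure offsets from dusk are reported in hours", {
  ev <- tibble::tibble(bird_id = "M01",
                       departure_time = as.POSIXct("2015-10-14 19:12:00",
                                                   tz = "UTC"),
                       confirmed = FALSE)
  dusk <- as.POSIXct("2015-10-14 17:00:00", tz = "UTC")
  expect_equal(departure_offset_from_dusk(ev, dusk), 2.2)
  ev0 <- ev
  ev0$departure_time <- dusk
  expect_equal(departure_offset_from_dusk(ev0, dusk), 0)
})

test_that("simulated departures are detected at the true instant", {
  cfg <- small_cfg(n_receivers = 2, seed = 23)
  m <- bird_meta("M03", "migrant", year = 2015)
  sim <- simulate_bird(cfg, m)
  ser <- classify_series(collapse_receivers(sim$records), thr,
                         start = min(sim$truth$timestamp),
                         end = max(sim$truth$timestamp))
  ev <- detect_departure(ser)
  expect_false(is.null(ev))
  expect_lte(abs(as.numeric(ev$departure_time -
                              sim$departure$departure_time,
                            units = "mins")), 2)
  # offset from dusk within the generative window
  offh <- departure_offset_from_dusk(ev, sim$departure$dusk)
  expect_gt(offh, 0)
  expect_lt(offh, 4.8)
})
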