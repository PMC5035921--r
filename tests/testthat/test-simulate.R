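test_that("the generator is deterministic and per-bird streams are stable", {
  cfg <- small_cfg(seed = 9)
  m <- bird_meta("M01", "migrant", year = 2015)
  a <- simulate_bird(cfg, m)
  b <- simulate_bird(cfg, m)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  # a different bird id gives a different stream
  m2 <- bird_meta("M02", "migrant", year = 2015)
  c2 <- simulate_bird(cfg, m2)
  expect_false(identical(a$departure$departure_time,
                         c2$departure$departure_time) &&
                 identical(a$records$signal_dbm[1:100],
                           c2$records$signal_dbm[1:100]))
  # different seeds move the departures
  cfg2 <- small_cfg(seed = 10)
  d2 <- simulate_bird(cfg2, m)
  expect_false(identical(a$departure$departure_time,
                         d2$departure$departure_time))
})

test_that("degenerate all-inactive config produces pure stillness", {
  cfg <- small_cfg(p_day = 0, p_night = 0, n_receivers = 1, p_detect = 1,
                   seed = 2)
  m <- bird_meta("R01", "resident", year = 2015)
  sim <- simulate_bird(cfg, m)
  expect_true(all(sim$truth$true_state == "inactive"))
  d <- pooled_deltas(sim$records)
  # deltas ~ Normal(0, sigma_still): sd close, no movement jumps
  expect_equal(sd(d * sample(c(-1, 1), length(d), TRUE)), cfg$sigma_still,
               tolerance = 0.05)
  expect_lt(max(d), 6 * cfg$sigma_still)
})

test_that("true day and night activity fractions match the generative rates", {
  cfg <- sim_config(start_date = "2015-10-01", end_date = "2015-10-08",
                    n_receivers = 1, storm_rate = 0, seed = 14)
  m <- bird_meta("R01", "resident", year = 2015)
  sim <- simulate_bird(cfg, m)
  tw <- twilight_table("2015-09-30", "2015-10-09", cfg$latitude,
                       cfg$longitude, cfg$tz_offset_hours)
  lab <- label_daynight(sim$truth$timestamp, tw)
  act <- sim$truth$true_state == "active"
  for (ph in c("day", "night")) {
    p_true <- if (ph == "day") cfg$p_day else cfg$p_night
    n <- sum(lab == ph)
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(mean(act[lab == ph]) - p_true), 3 * se)
  }
})

test_that("static tags produce the calibration-design record count", {
  cfg <- sim_config(seed = 4)
  recs <- lapply(sprintf("static%02d", 1:13), simulate_static_tag, cfg = cfg)
  expect_true(all(vapply(recs, nrow, integer(1)) == 10080))
  expect_equal(sum(vapply(recs, nrow, integer(1))), 13 * 10080)
})

test_that("departure truncation keeps a short take-off burst then silence", {
  cfg <- small_cfg(n_receivers = 1, p_detect = 1, seed = 6)
  m <- bird_meta("M01", "migrant", year = 2015)
  sim <- simulate_bird(cfg, m)
  dep <- sim$departure
  expect_false(is.null(dep))
  # last record is within 3 minutes after take-off
  expect_lte(as.numeric(max(sim$records$timestamp) - dep$takeoff_time,
                        units = "mins"), 3)
  expect_equal(max(sim$records$timestamp) + 60, dep$departure_time)
  # departure in (dusk, midnight]
  expect_gt(dep$takeoff_time, dep$dusk)
  expect_lte(dep$departure_time,
             arurhythm:::next_local_midnight(dep$dusk, 2) + 3 * 60)
  # residents keep records to the end of the window
  r <- simulate_bird(cfg, bird_meta("R01", "resident", year = 2015))
  expect_gt(as.numeric(max(r$records$timestamp)),
            as.numeric(max(sim$records$timestamp)))
})

test_that("simulate_departure truncates an arbitrary record stream", {
  rec <- make_records(rep(-100, 60))
  tk <- rec$timestamp[31]
  out <- simulate_departure(rec, tk, burst_min = 2)
  expect_equal(max(out$records$timestamp), tk + 60)
  expect_equal(out$departure_time, tk + 120)
  burst <- out$records[out$records$timestamp >= tk, ]
  expect_true(all(abs(diff(c(-100, burst$signal_dbm))) >= 8))
})

test_that("noise storms raise the noise floor above the ceiling", {
  rec <- make_records(rep(-100, 120))
  w <- c(rec$timestamp[31], rec$timestamp[90])
  set.seed(1)
  out <- inject_noise_storm(rec, w)
  sel <- out$timestamp >= w[1] & out$timestamp < w[2]
  expect_true(all(out$noise_dbm[sel] > -130))
  expect_equal(out$noise_dbm[!sel], rec$noise_dbm[!sel])
  # empty window leaves records unchanged
  out2 <- inject_noise_storm(rec, c(w[1], w[1]))
  expect_equal(out2, rec)
})

test_that("population bundle has the study-design structure", {
  cfg <- sim_config(n_migrants = 21, n_residents = 23,
                    n_departure_events = 24,
                    start_date = "2015-10-01", end_date = "2015-10-06",
                    departure_date_range = c("2015-10-03", "2015-10-03"),
                    n_receivers = 1, p_detect = 1, storm_rate = 0, seed = 8)
  pop <- simulate_population(cfg, n_static_tags = 2)
  expect_equal(sum(pop$seasons$status == "migrant"), 24)   # 24 events
  expect_equal(length(unique(pop$seasons$bird_id[pop$seasons$status == "migrant"])), 21)
  expect_equal(length(unique(pop$seasons$bird_id[pop$seasons$status == "resident"])), 23)
  expect_equal(nrow(pop$departures), 24)
  # repeat individuals sit in consecutive years
  reps <- table(pop$seasons$bird_id[pop$seasons$status == "migrant"])
  expect_equal(sort(as.integer(reps[reps > 1])), c(2, 3))
  yrs <- pop$seasons$year[pop$seasons$bird_id == names(which(reps == 3))]
  expect_equal(sort(diff(sort(yrs))), c(1, 1))
})

test_that("night truth shows no pre-departure trend without a ramp", {
  cfg <- small_cfg(n_receivers = 1, p_detect = 1, seed = 31)
  tw <- twilight_table("2015-09-24", "2015-10-13", cfg$latitude,
                       cfg$longitude, 2)
  slopes <- vapply(1:4, function(i) {
    m <- bird_meta(sprintf("M%02d", i), "migrant", year = 2015)
    sim <- simulate_bird(cfg, m)
    pre <- sim$truth[sim$truth$timestamp < sim$departure$takeoff_time, ]
    lab <- label_daynight(pre$timestamp, tw)
    night <- pre[lab == "night", ]
    day_idx <- as.numeric(arurhythm:::local_date(night$timestamp, 2) -
                            sim$departure$departure_date)
    fit <- lm(I(night$true_state == "active") ~ day_idx)
    summary(fit)$coefficients["day_idx", "t value"]
  }, numeric(1))
  # t-statistics behave like null draws: none should be extreme
  expect_true(all(abs(slopes) < 4))
})
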