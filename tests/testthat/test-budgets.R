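tw <- site_twilight()

test_that("budget bins count minutes and use the known-minute denominator", {
  # one local day starting at local midnight
  states <- rep("inactive", 1440)
  states[1:15] <- "active"                    # first bin: 15/15
  states[61:70] <- "active"                   # third bin: 10 active
  states[71:80] <- "unknown"                  # 10 unknown, 10 inactive
  states[121:150] <- "unknown"                # fifth bin: all unknown
  ser <- activity_series("b1", "2015-10-13 22:00:00", states)
  b <- activity_budget(ser, tw, 2)
  expect_equal(nrow(b), 48)
  expect_true(all(b$n_active + b$n_inactive + b$n_unknown == 30))
  expect_equal(b$proportion_active[1], 0.5)
  expect_equal(b$proportion_active[3], 0.5)   # 10 of 20 known
  expect_equal(b$n_unknown[3], 10)
  expect_true(is.na(b$proportion_active[5]))  # no known minutes, bin kept
  expect_equal(b$n_unknown[5], 30)
  # total-minute denominator on request
  b2 <- activity_budget(ser, tw, 2, denominator = "total")
  expect_equal(b2$proportion_active[3], 10 / 30)
  # time-of-day key: a bin starting 23:30 local keys at 23.5
  expect_equal(b$tod_hours[48], 23.5)
})

test_that("bin counts reconstruct the day's minute tally exactly", {
  set.seed(2)
  states <- sample(c("active", "inactive", "unknown"), 1440 * 2, TRUE)
  ser <- activity_series("b1", "2015-10-13 22:00:00", states)
  b <- activity_budget(ser, tw, 2)
  expect_equal(sum(b$n_active), sum(states == "active"))
  expect_equal(sum(b$n_inactive), sum(states == "inactive"))
  expect_equal(sum(b$n_unknown), sum(states == "unknown"))
})

test_that("alignment windows run from 7 days before to local midnight", {
  states <- rep("inactive", 1440 * 12)
  ser <- activity_series("m1", "2015-10-05 22:00:00", states)
  b <- activity_budget(ser, tw, 2)
  ev <- tibble::tibble(
    bird_id = "m1",
    departure_time = as.POSIXct("2015-10-14 19:40:00", tz = "UTC"),
    confirmed = FALSE)
  al <- align_to_departure(b, ev, quality = NULL, days = 7)
  # [Oct 7 21:40 local, Oct 15 00:00 local) in UTC
  expect_equal(min(al$start), as.POSIXct("2015-10-07 20:00:00", tz = "UTC"))
  expect_equal(max(al$start), as.POSIXct("2015-10-14 21:30:00", tz = "UTC"))
  expect_equal(sort(unique(al$days_before_departure)), -7:0)
  # never beyond local midnight of the departure night
  expect_lt(as.numeric(max(al$start)),
            as.numeric(as.POSIXct("2015-10-14 22:00:00", tz = "UTC")))
})

test_that("days failing the quality filter are dropped from the window", {
  states <- rep("inactive", 1440 * 12)
  ser <- activity_series("m1", "2015-10-05 22:00:00", states)
  b <- activity_budget(ser, tw, 2)
  ev <- tibble::tibble(
    bird_id = "m1",
    departure_time = as.POSIXct("2015-10-14 19:40:00", tz = "UTC"),
    confirmed = FALSE)
  qual <- tibble::tibble(date = as.Date("2015-10-06") + 0:8,
                         usable = TRUE)
  qual$usable[qual$date == as.Date("2015-10-10")] <- FALSE  # a 12% day
  al <- align_to_departure(b, ev, qual, days = 7)
  expect_false(as.Date("2015-10-10") %in%
                 arurhythm:::local_date(al$start, 2))
})

test_that("resident pairing is seeded, reproducible and uniform over one", {
  ev <- tibble::tibble(bird_id = "M01", event_id = "E01",
                       departure_time = as.POSIXct("2015-10-14 19:40:00",
                                                   tz = "UTC"),
                       confirmed = FALSE)
  p1 <- pair_resident(ev, c("R01", "R02", "R03"), seed = 11)
  p2 <- pair_resident(ev, c("R01", "R02", "R03"), seed = 11)
  expect_identical(p1, p2)
  expect_true(p1$resident_id %in% c("R01", "R02", "R03"))
  expect_equal(pair_resident(ev, "R02")$resident_id, "R02")
  expect_error(pair_resident(ev, character(0)), "no eligible resident")
})

test_that("lumping to 24 h keeps binomial bookkeeping", {
  b <- tibble::tibble(
    bird_id = "m1", tod_hours = c(23.5, 0), n_active = c(12, 0),
    n_inactive = c(10, 25), n_unknown = c(8, 5))
  l <- lump_to_24h(b)
  expect_equal(l$successes, c(12, 0))
  expect_equal(l$trials, c(22, 25))
  expect_equal(l$tod_hours[1], 23.5)
})

test_that("day/night summaries give group means over bird-days", {
  # identical birds at 35% day activity: SD zero
  mk <- function(id) {
    tibble::tibble(
      bird_id = id,
      start = as.POSIXct("2015-10-13 22:00:00", tz = "UTC") + 1800 * (0:47),
      n_active = rep(c(7L, 0L), c(24, 24)),
      n_inactive = rep(c(13L, 20L), c(24, 24)),
      n_unknown = 10L,
      daynight = rep(c("day", "night"), c(24, 24)))
  }
  g <- dplyr::bind_rows(mk("a"), mk("b"), mk("c"))
  s <- summarize_day_night(g, 2)
  expect_equal(s$mean_pct[s$daynight == "day"], 35)
  expect_equal(s$sd_pct[s$daynight == "day"], 0)
  expect_equal(s$mean_pct[s$daynight == "night"], 0)
  expect_error(summarize_day_night(g[0, ], 2), "empty")
})

test_that("group day/night summaries track the generative rates on truth", {
  cfg <- small_cfg(n_receivers = 1, p_detect = 1, seed = 77)
  tw2 <- twilight_table("2015-09-24", "2015-10-13", cfg$latitude,
                        cfg$longitude, 2)
  buds <- dplyr::bind_rows(lapply(1:3, function(i) {
    m <- bird_meta(sprintf("R%02d", i), "resident", year = 2015)
    sim <- simulate_bird(cfg, m)
    ser <- activity_series(m$bird_id, sim$truth$timestamp[1],
                           sim$truth$true_state)
    activity_budget(ser, tw2, 2)
  }))
  s <- summarize_day_night(buds, 2)
  day <- s[s$daynight == "day", ]
  expect_lt(abs(day$mean_pct - 35),
            3 * max(day$sd_pct / sqrt(day$n_bird_days), 0.5))
  night <- s[s$daynight == "night", ]
  expect_lt(abs(night$mean_pct - 2),
            3 * max(night$sd_pct / sqrt(night$n_bird_days), 0.5))
})

test_that("night means feed the August comparison correctly", {
  states <- rep("inactive", 1440 * 10)
  ser <- activity_series("b", "2015-08-09 22:00:00", states)
  tw_aug <- twilight_table("2015-08-09", "2015-08-20", 47.783, 9.033, 2)
  b <- activity_budget(ser, tw_aug, 2)
  # zero night activity -> 0.0
  v <- night_mean_activity(b, NULL, "2015-08-13", "2015-08-18")
  expect_equal(v, 0)
  # window without usable days -> NA with warning
  qual <- tibble::tibble(date = unique(arurhythm:::local_date(b$start, 2)),
                         usable = FALSE)
  expect_warning(v2 <- night_mean_activity(b, qual, "2015-08-13",
                                           "2015-08-18"), "excluded")
  expect_true(is.na(v2))
})
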