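#' Simulation configuration
#'
#' Defaults reproduce the study conditions of the original deployment: a
#' partially migratory songbird population at 47.783N 9.033E monitored from
#' early August through the end of October, with daytime active fraction
#' 0.35 and night-time 0.02 (the field estimates were approximately 37% and
#' 2%), 24 departure events from 21 migrant individuals and 23 residents,
#' departures on dates between 23 September and 26 October at 0.1--4.7 h
#' after civil dusk and always before local midnight, and a static-tag
#' signal-change scale chosen so that the 99% quantile of |delta| -- the
#' calibrated activity threshold -- is 4.0 dB.
#'
#' @param n_migrants,n_residents number of migrant / resident individuals.
#' @param n_departure_events total departure events; events beyond one per
#'   migrant are assigned to repeat individuals in consecutive years.
#' @param start_date,end_date season bounds (local calendar dates) of the
#'   base year; repeat-year seasons are shifted by whole years.
#' @param departure_date_range earliest and latest departure dates
#'   (`Date`s in the base-year season).
#' @param latitude,longitude site coordinates, decimal degrees.
#' @param tz_offset_hours constant UTC offset of site local time.
#' @param p_day,p_night per-minute probability of being active during civil
#'   day / night.
#' @param zugunruhe_ramp optional `function(days_before_departure)` returning
#'   the night-time activity probability for a migrant; `NULL` (default)
#'   gives the abrupt-switch scenario with constant `p_night` up to the
#'   night of departure.
#' @param departure_window numeric length-2: uniform bounds (hours after
#'   civil dusk) for the departure time; draws putting the departure after
#'   local midnight are rejected and redrawn.
#' @param sigma_still standard deviation (dB) of the one-minute signal
#'   change of a motionless tag.  Default `4 / qnorm(0.995)` so the
#'   half-normal 99% quantile equals the nominal 4.0 dB threshold.
#' @param p_exceed_active probability that an active minute produces a
#'   movement jump whose |delta| exceeds the nominal threshold (a free
#'   parameter of the generator: the field study gives no delta
#'   distribution for a moving bird).
#' @param storm_rate expected area-wide electronic-noise storms per week.
#' @param n_receivers number of ARUs hearing each bird.
#' @param p_detect long-run fraction of minutes each receiver hears the
#'   bird.  Dropouts are bursty, not independent minutes: each receiver
#'   alternates in-range and out-of-range episodes (geometric run lengths,
#'   mean out-of-range episode `mean_out_minutes`), as when a bird moves
#'   about the site.
#' @param mean_out_minutes mean length of an out-of-range episode.
#' @param noise_mean,noise_sd white-noise baseline (dBm).
#' @param seed master integer seed; each bird derives its own stream from
#'   (seed, bird_id, year) so adding birds never perturbs existing ones.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_migrants = 21,
                       n_residents = 23,
                       n_departure_events = 24,
                       start_date = "2015-08-10",
                       end_date = "2015-10-31",
                       departure_date_range = c("2015-09-23", "2015-10-26"),
                       latitude = 47.783,
                       longitude = 9.033,
                       tz_offset_hours = 2,
                       p_day = 0.35,
                       p_night = 0.02,
                       zugunruhe_ramp = NULL,
                       departure_window = c(0.1, 4.7),
                       sigma_still = 4.0 / stats::qnorm(0.995),
                       p_exceed_active = 0.9,
                       storm_rate = 1,
                       n_receivers = 3,
                       p_detect = 0.9,
                       mean_out_minutes = 10,
                       noise_mean = -141,
                       noise_sd = 2,
                       seed = 1L) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  departure_date_range <- as.Date(departure_date_range)
  if (end_date <= start_date) {
    stop("end_date must be after start_date")
  }
  stopifnot(p_night >= 0, p_day >= p_night, p_day <= 1)
  stopifnot(length(departure_window) == 2,
            departure_window[1] > 0, departure_window[2] < 12,
            departure_window[1] <= departure_window[2])
  stopifnot(sigma_still >= 0, p_exceed_active >= 0, p_exceed_active <= 1)
  stopifnot(n_departure_events >= n_migrants || n_migrants == 0)
  structure(
    list(n_migrants = n_migrants, n_residents = n_residents,
         n_departure_events = n_departure_events,
         start_date = start_date, end_date = end_date,
         departure_date_range = departure_date_range,
         latitude = latitude, longitude = longitude,
         tz_offset_hours = tz_offset_hours,
         p_day = p_day, p_night = p_night,
         zugunruhe_ramp = zugunruhe_ramp,
         departure_window = departure_window,
         sigma_still = sigma_still, p_exceed_active = p_exceed_active,
         storm_rate = storm_rate, n_receivers = n_receivers,
         p_detect = p_detect, mean_out_minutes = mean_out_minutes,
         noise_mean = noise_mean, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# deterministic per-bird substream seed from (master seed, bird_id, year)
bird_seed <- function(seed, bird_id, year = 0L) {
  h <- as.numeric(seed) %% 2147483647
  for (code in c(utf8ToInt(as.character(bird_id)), as.integer(year))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(max(h, 1))
}

# movement-offset path: piecewise-constant, jumps at `jump_idx` with the
# given magnitudes; jump direction is random but forced towards the centre
# once the offset leaves [-bound, bound], keeping signals in reception range
movement_path <- function(n, jump_idx, magnitudes, bound = 8) {
  m <- numeric(n)
  if (length(jump_idx) == 0) {
    return(m)
  }
  dirs <- sample(c(-1, 1), length(jump_idx), replace = TRUE)
  cur <- 0
  jumps <- numeric(length(jump_idx))
  for (j in seq_along(jump_idx)) {
    dir <- if (cur > bound) -1 else if (cur < -bound) 1 else dirs[j]
    cur <- cur + dir * magnitudes[j]
    jumps[j] <- cur
  }
  delta <- numeric(n)
  delta[jump_idx] <- diff(c(0, jumps))
  cumsum(delta)
}

# alternating in/out availability mask with geometric episode lengths
availability_mask <- function(n, p_in, mean_out) {
  if (p_in >= 1) {
    return(rep(TRUE, n))
  }
  mean_in <- mean_out * p_in / (1 - p_in)
  state <- stats::runif(1) < p_in
  out <- logical(0)
  while (length(out) < n) {
    len <- 1L + stats::rgeom(1, 1 / (if (state) mean_in else mean_out))
    out <- c(out, rep(state, len))
    state <- !state
  }
  out[seq_len(n)]
}

#' Simulate one bird's ARU record stream with known truth
#'
#' Per-minute Bernoulli activity with probability `p_night` at civil night
#' and `p_day` during civil day (optionally modified by the Zugunruhe ramp
#' for migrant nights).  The observed signal per receiver is a per-receiver
#' baseline (uniform on -110..-90 dBm) plus a shared movement offset that
#' jumps by at least the nominal 4 dB on active minutes (with probability
#' `p_exceed_active`) plus stationary noise scaled so a motionless tag's
#' one-minute |delta| is Normal(0, `sigma_still`).  Migrants get a 1--3 min
#' high-delta take-off burst at their departure instant and no records
#' afterwards.
#'
#' @param cfg a [sim_config()].
#' @param meta one-row bird metadata (see [bird_meta()]).
#' @param season_start,season_end season bounds; default from `cfg`.
#' @param twilight optional precomputed twilight table covering
#'   `season_start - 1 .. season_end + 1` (a shared cache when simulating
#'   many birds); computed on the fly when `NULL`.
#' @return A list with elements `records` (signal-record tibble),
#'   `truth` (tibble `bird_id`, `timestamp`, `true_state` with states
#'   active/inactive before departure and `absent` after) and `departure`
#'   (`NULL` for residents, else a one-row tibble with `takeoff_time` --
#'   start of the take-off burst -- and `departure_time`, the minute the
#'   tag left reception range, which is what the detector estimates).
#' @export
simulate_bird <- function(cfg, meta, season_start = cfg$start_date,
                          season_end = cfg$end_date, twilight = NULL) {
  stopifnot(inherits(cfg, "sim_config"), nrow(meta) == 1)
  season_start <- as.Date(season_start)
  season_end <- as.Date(season_end)
  if (season_end <= season_start) {
    stop("season_end must be after season_start")
  }
  off <- cfg$tz_offset_hours
  set.seed(bird_seed(cfg$seed, meta$bird_id, meta$year))

  t0 <- as.POSIXct(paste(season_start, "00:00:00"), tz = "UTC") - off * 3600
  n_min <- as.integer(as.numeric(season_end - season_start)) * 1440L
  tgrid <- t0 + 60 * (0:(n_min - 1L))

  tw <- if (is.null(twilight)) {
    twilight_table(season_start - 1, season_end + 1,
                   cfg$latitude, cfg$longitude, off)
  } else {
    twilight
  }
  is_day <- label_daynight(tgrid, tw) == "day"
  p <- ifelse(is_day, cfg$p_day, cfg$p_night)

  departure <- NULL
  if (identical(meta$status, "migrant")) {
    # year-shifted seasons keep the same month-day departure window
    k <- as.integer(format(season_start, "%Y")) -
      as.integer(format(cfg$start_date, "%Y"))
    same_md <- function(d) {
      as.Date(sprintf("%d-%s", as.integer(format(d, "%Y")) + k,
                      format(d, "%m-%d")))
    }
    date_lo <- max(same_md(cfg$departure_date_range[1]), season_start + 1)
    date_hi <- min(same_md(cfg$departure_date_range[2]), season_end - 2)
    if (date_hi < date_lo) {
      stop("season too short to place a departure inside the departure window")
    }
    dep_date <- date_lo + sample.int(as.integer(date_hi - date_lo) + 1L, 1) - 1L
    dusk <- tw$civil_dusk[match(dep_date, tw$date)]
    midnight <- next_local_midnight(dusk, off)
    repeat {
      dep_off <- runif(1, cfg$departure_window[1], cfg$departure_window[2])
      takeoff <- dusk + dep_off * 3600
      if (takeoff < midnight) break
    }
    takeoff <- floor_minute(takeoff)
    burst <- sample(1:3, 1)
    departure <- tibble::tibble(
      bird_id = meta$bird_id, year = meta$year,
      departure_date = dep_date,
      takeoff_time = takeoff,
      departure_time = takeoff + burst * 60,
      dusk = dusk
    )
    if (!is.null(cfg$zugunruhe_ramp)) {
      night_idx <- which(!is_day)
      dbd <- as.numeric(local_date(tgrid[night_idx], off) - dep_date)
      p[night_idx] <- pmin(1, pmax(0, cfg$zugunruhe_ramp(dbd)))
    }
  }

  active <- stats::rbinom(n_min, 1, p) == 1

  jump <- active & stats::runif(n_min) < cfg$p_exceed_active
  mags <- numeric(n_min)
  mags[jump] <- 4.0 + stats::rexp(sum(jump), rate = 1 / 2)

  last_idx <- n_min
  if (!is.null(departure)) {
    tk_idx <- as.integer((as.numeric(departure$takeoff_time) -
                            as.numeric(t0)) / 60) + 1L
    burst_idx <- seq(tk_idx, length.out = as.integer(
      (as.numeric(departure$departure_time) -
         as.numeric(departure$takeoff_time)) / 60))
    active[burst_idx] <- TRUE
    jump[burst_idx] <- TRUE
    mags[burst_idx] <- 8.0 + stats::rexp(length(burst_idx), rate = 1)
    last_idx <- max(burst_idx)
  }

  m <- movement_path(n_min, which(jump), mags[jump])

  recs <- vector("list", cfg$n_receivers)
  for (r in seq_len(cfg$n_receivers)) {
    baseline <- stats::runif(1, -110, -90)
    eps <- stats::rnorm(n_min, 0, cfg$sigma_still / sqrt(2))
    det <- availability_mask(n_min, cfg$p_detect, cfg$mean_out_minutes)
    idx <- which(det & seq_len(n_min) <= last_idx)
    if (!is.null(departure)) {
      # take-off burst is loud and always heard
      idx <- sort(union(idx, intersect(burst_idx, seq_len(last_idx))))
    }
    if (length(idx) == 0) next
    recs[[r]] <- tibble::tibble(
      timestamp = tgrid[idx],
      tag_id = meta$bird_id,
      signal_dbm = baseline + m[idx] + eps[idx],
      noise_dbm = stats::rnorm(length(idx), cfg$noise_mean, cfg$noise_sd),
      receiver_id = sprintf("ARU%d", r)
    )
  }
  records <- dplyr::bind_rows(recs)
  records <- records[order(records$tag_id, records$receiver_id,
                           records$timestamp), ]

  true_state <- ifelse(active, "active", "inactive")
  if (last_idx < n_min) {
    true_state[(last_idx + 1L):n_min] <- "absent"
  }
  truth <- tibble::tibble(bird_id = meta$bird_id, timestamp = tgrid,
                          true_state = true_state)
  list(records = records, truth = truth, departure = departure)
}

#' Simulate a static reference tag
#'
#' A motionless tag: constant baseline, stationary noise such that the
#' one-minute signal change is Normal(0, `sigma_still`), one record per
#' minute with no dropouts (the calibration experiment design).
#'
#' @param cfg a [sim_config()].
#' @param tag_id identifier of the reference tag.
#' @param start first instant (default: local midnight of season start).
#' @param duration_days length of the deployment (default 7, one week).
#' @param receiver_id receiver logging the tag.
#' @return signal-record tibble with `duration_days * 1440` rows.
#' @export
simulate_static_tag <- function(cfg, tag_id = "static01", start = NULL,
                                duration_days = 7, receiver_id = "ARU1") {
  stopifnot(duration_days > 0)
  if (is.null(start)) {
    start <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC") -
      cfg$tz_offset_hours * 3600
  }
  set.seed(bird_seed(cfg$seed, tag_id, 0L))
  n <- as.integer(round(duration_days * 1440))
  baseline <- stats::runif(1, -110, -90)
  eps <- if (cfg$sigma_still > 0) {
    stats::rnorm(n, 0, cfg$sigma_still / sqrt(2))
  } else {
    numeric(n)
  }
  tibble::tibble(
    timestamp = utc_time(start) + 60 * (0:(n - 1L)),
    tag_id = tag_id,
    signal_dbm = baseline + eps,
    noise_dbm = stats::rnorm(n, cfg$noise_mean, cfg$noise_sd),
    receiver_id = receiver_id
  )
}

#' Truncate a record stream at a departure
#'
#' Minutes before `takeoff_time` are unchanged; the 1--3 take-off minutes
#' (`burst_min`) get high-delta signals (|delta| >= 8 dB, reproducing actual
#' take-off behaviour); afterwards the bird is out of reception range and
#' no records remain.
#'
#' @param records signal-record tibble for one bird.
#' @param takeoff_time POSIXct instant of take-off.
#' @param burst_min number of take-off minutes (1--3).
#' @return A list: `records` (modified tibble) and `departure_time`
#'   (first minute with no signal).
#' @export
simulate_departure <- function(records, takeoff_time, burst_min = 2) {
  stopifnot(burst_min >= 1, burst_min <= 3)
  tk <- floor_minute(takeoff_time)
  dep <- tk + burst_min * 60
  out <- records[records$timestamp < tk, , drop = FALSE]
  bursts <- lapply(unique(out$receiver_id), function(rid) {
    prev <- out[out$receiver_id == rid, ]
    if (nrow(prev) == 0) return(NULL)
    base <- prev$signal_dbm[nrow(prev)]
    sig <- base + cumsum(sample(c(-1, 1), burst_min, TRUE) *
                           (8 + stats::rexp(burst_min, 1)))
    tibble::tibble(
      timestamp = tk + 60 * (0:(burst_min - 1L)),
      tag_id = prev$tag_id[1],
      signal_dbm = sig,
      noise_dbm = stats::rnorm(burst_min, mean(prev$noise_dbm), 1),
      receiver_id = rid
    )
  })
  res <- dplyr::bind_rows(c(list(out), bursts))
  res <- res[order(res$tag_id, res$receiver_id, res$timestamp), ]
  list(records = res, departure_time = dep)
}

#' Inject an electronic-noise storm
#'
#' Within the window, the recorded noise floor is raised above the -130 dBm
#' ceiling (as under stormy weather) and the signal picks up jitter.  The
#' downstream classifier marks such minutes unknown.
#'
#' @param records signal-record tibble.
#' @param window POSIXct length-2: storm start and end (UTC).
#' @param noise_range dBm range of the elevated noise floor.
#' @param jitter_sd dB standard deviation of added signal jitter.
#' @return Modified records tibble.
#' @export
inject_noise_storm <- function(records, window, noise_range = c(-129.5, -118),
                               jitter_sd = 3) {
  if (nrow(records) == 0) return(records)
  sel <- records$timestamp >= window[1] & records$timestamp < window[2]
  n <- sum(sel)
  if (n > 0) {
    records$noise_dbm[sel] <- stats::runif(n, noise_range[1], noise_range[2])
    records$signal_dbm[sel] <- records$signal_dbm[sel] +
      stats::rnorm(n, 0, jitter_sd)
  }
  records
}

#' Simulate a whole study population
#'
#' Builds metadata for `n_migrants` migrants and `n_residents` residents,
#' assigns `n_departure_events` departure events (extra events go to repeat
#' individuals in consecutive later years, as in the field data set),
#' simulates every bird-season, the 13 static calibration tags, and
#' area-wide noise storms.
#'
#' @param cfg a [sim_config()].
#' @param n_static_tags number of static reference tags (default 13).
#' @return A list bundle: `cfg`, `meta` (bird metadata with one row per
#'   bird-season), `records` (all bird signal records), `static_records`,
#'   `truth` (list of per-season truth tibbles keyed by `bird_id.year`),
#'   `departures` (one row per event) and `storms`.
#' @export
simulate_population <- function(cfg, n_static_tags = 13) {
  base_year <- as.integer(format(cfg$start_date, "%Y"))

  mig_ids <- sprintf("M%02d", seq_len(cfg$n_migrants))
  res_ids <- sprintf("R%02d", seq_len(cfg$n_residents))

  # departure events: one per migrant, extras to repeat birds in later years
  ev_bird <- mig_ids
  ev_year <- rep(0L, cfg$n_migrants)
  extra <- cfg$n_departure_events - cfg$n_migrants
  if (cfg$n_migrants > 0 && extra > 0) {
    # up to 2 extra events per repeat bird (a 3-departure and a 2-departure
    # individual reproduce the field data set when extra = 3)
    rep_birds <- rep(rev(mig_ids), each = 2, length.out = extra)
    counts <- table(rep_birds)
    for (b in names(counts)) {
      ev_bird <- c(ev_bird, rep(b, counts[[b]]))
      ev_year <- c(ev_year, seq_len(counts[[b]]))
    }
  }
  year_offsets <- sort(unique(ev_year))
  res_year <- if (length(year_offsets) > 0 && cfg$n_residents > 0) {
    year_offsets[(seq_len(cfg$n_residents) - 1L) %% length(year_offsets) + 1L]
  } else {
    integer(0)
  }

  set.seed(cfg$seed)
  mig_sex <- sample(c("F", "M", "unknown"), length(ev_bird), TRUE,
                    prob = c(9, 8, 4) / 21)
  res_sex <- sample(c("F", "M", "unknown"), cfg$n_residents, TRUE,
                    prob = c(3, 19, 1) / 23)

  seasons <- tibble::tibble(
    bird_id = c(ev_bird, res_ids),
    status = rep(c("migrant", "resident"), c(length(ev_bird), cfg$n_residents)),
    sex = c(mig_sex, res_sex),
    year_offset = c(ev_year, res_year),
    year = base_year + c(ev_year, res_year)
  )
  seasons$event_id <- NA_character_
  seasons$event_id[seasons$status == "migrant"] <-
    sprintf("E%02d", seq_len(length(ev_bird)))

  shift_date <- function(d, k) {
    # same month-day in year + k (Feb 29 never occurs in the study window)
    as.Date(sprintf("%d-%s", as.integer(format(d, "%Y")) + k,
                    format(d, "%m-%d")))
  }

  tw_cache <- lapply(setNames(year_offsets, year_offsets), function(k) {
    twilight_table(shift_date(cfg$start_date, k) - 1,
                   shift_date(cfg$end_date, k) + 1,
                   cfg$latitude, cfg$longitude, cfg$tz_offset_hours)
  })

  all_records <- vector("list", nrow(seasons))
  truth_list <- list()
  departures <- list()
  for (i in seq_len(nrow(seasons))) {
    s <- seasons[i, ]
    meta_i <- bird_meta(s$bird_id, s$status, s$sex, "adult", s$year)
    sim <- simulate_bird(cfg, meta_i,
                         season_start = shift_date(cfg$start_date, s$year_offset),
                         season_end = shift_date(cfg$end_date, s$year_offset),
                         twilight = tw_cache[[as.character(s$year_offset)]])
    all_records[[i]] <- sim$records
    truth_list[[paste(s$bird_id, s$year, sep = ".")]] <- sim$truth
    if (!is.null(sim$departure)) {
      departures[[length(departures) + 1L]] <-
        dplyr::mutate(sim$departure, event_id = s$event_id)
    }
  }
  records <- dplyr::bind_rows(all_records)

  # area-wide noise storms, per season year
  set.seed(bird_seed(cfg$seed, "storms", 0L))
  n_weeks <- as.numeric(cfg$end_date - cfg$start_date) / 7
  storms <- list()
  for (k in year_offsets) {
    n_storms <- stats::rpois(1, cfg$storm_rate * n_weeks)
    if (n_storms == 0) next
    s0 <- as.POSIXct(paste(shift_date(cfg$start_date, k), "00:00:00"),
                     tz = "UTC") - cfg$tz_offset_hours * 3600
    span <- as.numeric(cfg$end_date - cfg$start_date) * 86400
    for (j in seq_len(n_storms)) {
      st <- s0 + runif(1, 0, span - 4 * 3600)
      dur <- runif(1, 30, 240) * 60
      w <- c(floor_minute(st), floor_minute(st + dur))
      records <- inject_noise_storm(records, w)
      storms[[length(storms) + 1L]] <-
        tibble::tibble(start = w[1], end = w[2], year = base_year + k)
    }
  }

  static_records <- dplyr::bind_rows(lapply(
    sprintf("static%02d", seq_len(n_static_tags)),
    function(id) simulate_static_tag(cfg, tag_id = id)
  ))

  meta <- bird_meta(
    bird_id = seasons$bird_id, status = seasons$status,
    sex = seasons$sex, age = "adult", year = seasons$year
  )

  list(cfg = cfg, meta = meta, seasons = seasons, records = records,
       static_records = static_records, truth = truth_list,
       departures = dplyr::bind_rows(departures),
       storms = dplyr::bind_rows(storms))
}
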