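#' 30-minute activity budgets
#'
#' Aggregates a per-minute activity series into clock-aligned half-open
#' half-hour bins.  Each bin carries the minute counts by state, the
#' proportion of *known* minutes that were active (missing when the bin has
#' no known minute), a day/night label taken at the bin midpoint, and the
#' local time-of-day key of the bin start in decimal hours.
#'
#' The known-minute denominator is the default because the separate <10%
#' daily-uncertainty filter already bounds the unknown share; set
#' `denominator = "total"` to divide by all 30 minutes instead.
#'
#' @param series an [activity_series()].
#' @param twilight twilight table covering the series dates
#'   (see [twilight_table()]).
#' @param tz_offset_hours site local-time offset (default +2).
#' @param denominator `"known"` (default) or `"total"`.
#' @param bird_id identifier stored in the output (default: series tag).
#' @return tibble with columns `bird_id`, `start`, `tod_hours`, `n_active`,
#'   `n_inactive`, `n_unknown`, `proportion_active`, `daynight`.
#' @export
activity_budget <- function(series, twilight, tz_offset_hours = 2,
                            denominator = c("known", "total"),
                            bird_id = series$tag_id) {
  denominator <- match.arg(denominator)
  ts <- series_timestamps(series)
  bin <- floor(as.numeric(ts) / 1800) * 1800
  st <- factor(series$states, c("active", "inactive", "unknown"))
  counts <- table(bin, st)
  starts <- as.POSIXct(as.numeric(rownames(counts)),
                       origin = "1970-01-01", tz = "UTC")
  n_act <- as.integer(counts[, "active"])
  n_ina <- as.integer(counts[, "inactive"])
  n_unk <- as.integer(counts[, "unknown"])
  known <- n_act + n_ina
  prop <- ifelse(known > 0,
                 n_act / if (denominator == "known") known else 30L,
                 NA_real_)
  tibble::tibble(
    bird_id = bird_id,
    start = starts,
    tod_hours = local_hour(starts, tz_offset_hours),
    n_active = n_act,
    n_inactive = n_ina,
    n_unknown = n_unk,
    proportion_active = prop,
    daynight = label_daynight(starts + 900, twilight)
  )
}

#' Align budgets to a departure event
#'
#' Retains the bins in the window from `days` days before the departure
#' instant up to local midnight of the departure night, annotates each bin
#' with `days_before_departure` (local-date offset: negative before, 0 on
#' the departure day), and drops bins on days failing the daily quality
#' filter.
#'
#' @param budgets budget tibble from [activity_budget()].
#' @param event one-row departure-event tibble (needs `departure_time`).
#' @param quality daily-quality tibble from [daily_quality()]; `NULL` skips
#'   the filter.
#' @param days window length before departure (default 7).
#' @param tz_offset_hours site local-time offset (default +2).
#' @return The filtered, annotated budget tibble.
#' @export
align_to_departure <- function(budgets, event, quality = NULL, days = 7,
                               tz_offset_hours = 2) {
  dep <- event$departure_time
  w_start <- dep - days * 86400
  w_end <- next_local_midnight(dep, tz_offset_hours)
  out <- budgets[budgets$start >= w_start & budgets$start < w_end, ,
                 drop = FALSE]
  bin_date <- local_date(out$start, tz_offset_hours)
  dep_date <- local_date(dep, tz_offset_hours)
  out$days_before_departure <- as.numeric(bin_date - dep_date)
  if (!is.null(quality)) {
    bad <- quality$date[!quality$usable]
    out <- out[!(bin_date %in% bad), , drop = FALSE]
  }
  out
}

#' Randomly pair a departure event with a resident
#'
#' Uniform random choice among residents with usable data coverage over the
#' event window ("present at the breeding ground at the same time").
#' Residents may be reused across events.  Draws come from R's RNG stream;
#' seed the session (or pass `seed`) for reproducibility.
#'
#' @param event one-row departure-event tibble.
#' @param eligible_ids character vector of eligible resident ids.
#' @param seed optional integer seed applied before the draw.
#' @return one-row tibble: `event_id` (if present in `event`), `migrant_id`,
#'   `resident_id`.
#' @export
pair_resident <- function(event, eligible_ids, seed = NULL) {
  if (length(eligible_ids) == 0) {
    stop("no eligible resident covers the window of the departure event at ",
         format(event$departure_time, "%Y-%m-%d %H:%M UTC"))
  }
  if (!is.null(seed)) set.seed(seed)
  chosen <- if (length(eligible_ids) == 1) {
    eligible_ids
  } else {
    sample(eligible_ids, 1)
  }
  tibble::tibble(
    event_id = if ("event_id" %in% names(event)) event$event_id else NA_character_,
    migrant_id = event$bird_id,
    resident_id = chosen
  )
}

#' Lump aligned budgets into one 24-hour day
#'
#' Re-keys each bin by its local time-of-day so that the 7 pre-departure
#' days stack into a single 24 h period: one observation per half-hour slot
#' per day per bird, keeping the (successes = active, trials = known
#' minutes) pair needed for binomial modelling.
#'
#' @param aligned aligned budget tibble from [align_to_departure()] (any
#'   extra columns such as `bird_id`, `status` are carried through).
#' @return The same tibble with `successes` and `trials` columns,
#'   guaranteed `tod_hours` keys in [0, 24).
#' @export
lump_to_24h <- function(aligned) {
  out <- aligned
  out$successes <- out$n_active
  out$trials <- out$n_active + out$n_inactive
  out
}

#' Day/night activity summary of a group
#'
#' Per bird-day percent of known minutes active, split by the day/night
#' label, then mean and SD across bird-days in the group.
#'
#' @param budgets budget tibble (needs `bird_id`, `start`, counts,
#'   `daynight`).
#' @param tz_offset_hours site local-time offset (default +2).
#' @return tibble: `daynight`, `mean_pct`, `sd_pct`, `n_bird_days`.
#' @export
summarize_day_night <- function(budgets, tz_offset_hours = 2) {
  if (nrow(budgets) == 0) {
    stop("empty budget group")
  }
  b <- budgets
  b$date <- local_date(b$start, tz_offset_hours)
  per <- dplyr::summarise(
    dplyr::group_by(b, bird_id, date, daynight),
    pct = 100 * sum(n_active) / pmax(sum(n_active) + sum(n_inactive), 1L),
    known = sum(n_active) + sum(n_inactive),
    .groups = "drop"
  )
  per <- per[per$known > 0, ]
  dplyr::summarise(
    dplyr::group_by(per, daynight),
    mean_pct = mean(pct),
    sd_pct = stats::sd(pct),
    n_bird_days = dplyr::n(),
    .groups = "drop"
  )
}

#' Mean night activity of one bird over a date window
#'
#' Mean proportion of known night minutes active over the usable days in
#' `[from, to]` (local dates).  Returns `NA` with a warning when the window
#' has no usable night data, in which case the bird should be excluded.
#'
#' @param budgets budget tibble for one bird.
#' @param quality daily-quality tibble for the same bird (`NULL` skips the
#'   filter).
#' @param from,to window bounds, local calendar dates (inclusive).
#' @param tz_offset_hours site local-time offset (default +2).
#' @return Scalar mean night activity (proportion), or `NA_real_`.
#' @export
night_mean_activity <- function(budgets, quality, from, to,
                                tz_offset_hours = 2) {
  d <- local_date(budgets$start, tz_offset_hours)
  sel <- d >= as.Date(from) & d <= as.Date(to) & budgets$daynight == "night"
  if (!is.null(quality)) {
    sel <- sel & d %in% quality$date[quality$usable]
  }
  b <- budgets[sel, , drop = FALSE]
  known <- sum(b$n_active) + sum(b$n_inactive)
  if (nrow(b) == 0 || known == 0) {
    warning("no usable night data in window ", from, "..", to,
            "; bird excluded")
    return(NA_real_)
  }
  sum(b$n_active) / known
}

#' Pre-departure and August night means for the seasonal comparison
#'
#' Two scalar summaries per bird: mean night activity during the ten days
#' before the departure instant, and during 13--20 August of the same year.
#'
#' @param budgets budget tibble for one bird.
#' @param quality daily-quality tibble for the same bird.
#' @param departure_time POSIXct departure instant anchoring the
#'   pre-migration window (for residents: the paired migrant's departure).
#' @param year study year for the August window.
#' @param pre_days length of the pre-departure window (default 10).
#' @param tz_offset_hours site local-time offset (default +2).
#' @return tibble with `period` (`"august"`, `"pre_migration"`) and
#'   `night_mean`.
#' @export
night_mean_series <- function(budgets, quality, departure_time, year,
                              pre_days = 10, tz_offset_hours = 2) {
  dep_date <- local_date(departure_time, tz_offset_hours)
  pre <- night_mean_activity(budgets, quality,
                             from = dep_date - pre_days, to = dep_date - 1,
                             tz_offset_hours = tz_offset_hours)
  aug <- night_mean_activity(budgets, quality,
                             from = as.Date(sprintf("%d-08-13", year)),
                             to = as.Date(sprintf("%d-08-20", year)),
                             tz_offset_hours = tz_offset_hours)
  tibble::tibble(period = c("august", "pre_migration"),
                 night_mean = c(aug, pre))
}
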