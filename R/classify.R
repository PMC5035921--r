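#' Classify one tag-minute
#'
#' Applies the classification rules in fixed order.  A minute is `unknown`
#' when (1) there is no record, (2) the signal is below the minimum-signal
#' threshold, (3) the signal-to-noise gap is under the gap minimum, (4) the
#' noise floor exceeds the noise ceiling (area-wide electronic noise), or
#' (5) the previous minute is missing, not exactly one minute earlier, or
#' itself unusable under rules 2--4 (the one-minute signal change is then
#' undefined).  Otherwise the minute is `active` when |delta| strictly
#' exceeds the activity threshold and `inactive` otherwise (a change exactly
#' at the threshold is inactive).
#'
#' @param prev,curr one-row signal-record tibbles (best receiver for the
#'   previous / current minute), or `NULL` when missing.
#' @param thr a [cal_thresholds()].
#' @return `"active"`, `"inactive"` or `"unknown"`.
#' @export
classify_minute <- function(prev, curr, thr) {
  usable <- function(rec) {
    !is.null(rec) &&
      rec$signal_dbm >= thr$min_signal_dbm &&
      (rec$signal_dbm - rec$noise_dbm) >= thr$min_gap_db &&
      rec$noise_dbm <= thr$noise_ceiling_dbm
  }
  if (!usable(curr)) {
    return("unknown")
  }
  if (!usable(prev)) {
    return("unknown")
  }
  gap <- as.numeric(floor_minute(curr$timestamp)) -
    as.numeric(floor_minute(prev$timestamp))
  if (gap != 60) {
    return("unknown")
  }
  delta <- abs(curr$signal_dbm - prev$signal_dbm)
  if (delta > thr$activity_delta_db) "active" else "inactive"
}

#' Classify a full record stream into an activity series
#'
#' Vectorised application of the [classify_minute()] rules over the whole
#' span of one tag's best-receiver records (see [collapse_receivers()]).
#' Minutes without a record are `unknown`; the output has exactly one state
#' per minute spanned, with no gaps.
#'
#' @param records signal-record tibble for one tag, at most one row per
#'   minute (strongest receiver already selected).
#' @param thr a [cal_thresholds()].
#' @param start,end optional span bounds (POSIXct); default to the first
#'   and last record minute.
#' @return An [activity_series()].
#' @export
classify_series <- function(records, thr, start = NULL, end = NULL) {
  if (nrow(records) == 0 && (is.null(start) || is.null(end))) {
    stop("cannot classify an empty record stream without explicit span")
  }
  tag <- if (nrow(records) > 0) records$tag_id[1] else "unknown-tag"
  mins <- floor_minute(records$timestamp)
  if (anyDuplicated(mins)) {
    stop("records contain more than one row per minute; ",
         "run collapse_receivers() first")
  }
  t_start <- floor_minute(if (is.null(start)) min(mins) else utc_time(start))
  t_end <- floor_minute(if (is.null(end)) max(mins) else utc_time(end))
  n <- as.integer((as.numeric(t_end) - as.numeric(t_start)) / 60) + 1L

  idx <- as.integer((as.numeric(mins) - as.numeric(t_start)) / 60) + 1L
  keep <- idx >= 1 & idx <= n
  idx <- idx[keep]

  sig <- rep(NA_real_, n)
  noi <- rep(NA_real_, n)
  sig[idx] <- records$signal_dbm[keep]
  noi[idx] <- records$noise_dbm[keep]

  usable <- !is.na(sig) &
    sig >= thr$min_signal_dbm &
    (sig - noi) >= thr$min_gap_db &
    noi <= thr$noise_ceiling_dbm

  prev_usable <- c(FALSE, usable[-n])
  prev_sig <- c(NA_real_, sig[-n])
  delta <- abs(sig - prev_sig)

  states <- rep("unknown", n)
  ok <- usable & prev_usable
  states[ok] <- ifelse(delta[ok] > thr$activity_delta_db, "active", "inactive")
  activity_series(tag, t_start, states)
}

#' Daily quality of an activity series
#'
#' Fraction of unknown minutes per local calendar day.  A day is usable for
#' activity budgets only when its unknown fraction is strictly under 10%
#' (the conservative uncertainty filter).
#'
#' @param series an [activity_series()].
#' @param tz_offset_hours site local-time offset (default +2).
#' @param threshold maximum tolerated unknown fraction (exclusive).
#' @return tibble with one row per local day: `date`, `n_minutes`,
#'   `unknown_fraction`, `usable`.
#' @export
daily_quality <- function(series, tz_offset_hours = 2, threshold = 0.10) {
  d <- local_date(series_timestamps(series), tz_offset_hours)
  unk <- series$states == "unknown"
  agg <- tapply(unk, d, function(x) c(length(x), mean(x)))
  dates <- as.Date(names(agg))
  m <- do.call(rbind, agg)
  tibble::tibble(
    date = dates,
    n_minutes = as.integer(unname(m[, 1])),
    unknown_fraction = unname(m[, 2]),
    usable = unname(m[, 2] < threshold)
  )
}

#' Detect a departure event
#'
#' Finds the first time stamp after which the signal is permanently absent:
#' the start of the terminal run of unknown states.  An event is returned
#' only when that run lasts at least `min_absence` (default 24 h), guarding
#' against long same-night dropouts; the `confirmed` flag is `FALSE` so the
#' event can be queued for human review, replacing the visual confirmation
#' step of the field protocol.  Signal that is absent but reappears later is
#' unknown time, not a departure.
#'
#' @param series an [activity_series()].
#' @param min_absence_hours minimum terminal-absence duration in hours.
#' @param bird_id identifier attached to the event (default: series tag).
#' @return A one-row tibble (`bird_id`, `departure_time`, `confirmed`), or
#'   `NULL` when the series does not end in a sufficiently long unknown run.
#' @export
detect_departure <- function(series, min_absence_hours = 24,
                             bird_id = series$tag_id) {
  known <- which(series$states != "unknown")
  if (length(known) == 0) {
    warning("series is entirely unknown; no known baseline, ",
            "no departure detected")
    return(NULL)
  }
  last_known <- max(known)
  n <- length(series$states)
  if (last_known == n) {
    return(NULL)
  }
  run_minutes <- n - last_known
  if (run_minutes < min_absence_hours * 60) {
    return(NULL)
  }
  tibble::tibble(
    bird_id = bird_id,
    departure_time = series$start + 60 * last_known,
    confirmed = FALSE
  )
}

#' Departure offset from civil dusk
#'
#' @param event one-row departure-event tibble (see [detect_departure()]).
#' @param dusk POSIXct civil dusk of the departure night.
#' @return Signed offset in hours (departure minus dusk).
#' @export
departure_offset_from_dusk <- function(event, dusk) {
  as.numeric(event$departure_time - dusk, units = "hours")
}
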