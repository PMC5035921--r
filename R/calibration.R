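#' Calibration thresholds
#'
#' Container for the four classification thresholds and the three
#' calibration parameters that generate them.  The shipped defaults are the
#' values used in the original field deployment: activity threshold 4.0 dB
#' (99% upper quantile of static-tag signal change), minimum usable signal
#' -127.0 dBm (4 dB above the mean upper 95% quantile of white noise),
#' signal-to-noise gap minimum 10 dB, and noise ceiling -130 dBm.
#'
#' @param activity_delta_db minimum absolute one-minute signal change (dB)
#'   for a minute to be called active.
#' @param min_signal_dbm minimum usable signal strength (dBm).
#' @param noise_ceiling_dbm noise level (dBm) above which the whole area is
#'   considered noise-stormed and minutes are unknown.
#' @param min_gap_db minimum signal-minus-noise gap (dB).
#' @param quantile_activity quantile of pooled static-tag |delta| used by
#'   [activity_threshold()].
#' @param quantile_noise per-group noise quantile used by
#'   [min_signal_threshold()].
#' @param noise_margin_db margin added to the mean noise quantile.
#' @return An object of class `cal_thresholds`.
#' @export
cal_thresholds <- function(activity_delta_db = 4.0,
                           min_signal_dbm = -127.0,
                           noise_ceiling_dbm = -130.0,
                           min_gap_db = 10.0,
                           quantile_activity = 0.99,
                           quantile_noise = 0.95,
                           noise_margin_db = 4.0) {
  stopifnot(activity_delta_db > 0, min_gap_db > 0,
            quantile_activity > 0, quantile_activity < 1,
            quantile_noise > 0, quantile_noise < 1)
  structure(
    list(activity_delta_db = activity_delta_db,
         min_signal_dbm = min_signal_dbm,
         noise_ceiling_dbm = noise_ceiling_dbm,
         min_gap_db = min_gap_db,
         quantile_activity = quantile_activity,
         quantile_noise = quantile_noise,
         noise_margin_db = noise_margin_db),
    class = "cal_thresholds"
  )
}

#' @rdname cal_thresholds
#' @export
default_thresholds <- function() cal_thresholds()

#' @export
print.cal_thresholds <- function(x, ...) {
  cat("<cal_thresholds>\n",
      "  activity |delta| > ", x$activity_delta_db, " dB (q = ",
      x$quantile_activity, ")\n",
      "  min signal  >= ", x$min_signal_dbm, " dBm (noise q = ",
      x$quantile_noise, " + ", x$noise_margin_db, " dB)\n",
      "  min S/N gap >= ", x$min_gap_db, " dB\n",
      "  noise ceiling <= ", x$noise_ceiling_dbm, " dBm\n", sep = "")
  invisible(x)
}

#' Write / read thresholds as YAML
#'
#' @param thr a `cal_thresholds` object.
#' @param path file path.
#' @return `write_thresholds()` returns `path` invisibly;
#'   `read_thresholds()` returns a `cal_thresholds`.
#' @export
write_thresholds <- function(thr, path) {
  yaml::write_yaml(unclass(thr), path)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  do.call(cal_thresholds, yaml::read_yaml(path))
}

#' Pooled one-minute signal changes of static tags
#'
#' For every (tag, receiver) stream, takes the absolute difference of signal
#' strength between records exactly one minute-bin apart and pools them
#' across tags and receivers.  Pairs spanning gaps (missing minutes) are
#' excluded.  The change is pooled unsigned: the activity rule thresholds
#' the magnitude of signal change, for which only |delta| is meaningful.
#'
#' @param static_records signal-record tibble from one or more static
#'   reference tags (any number of receivers).
#' @return Numeric vector of |delta| values in dB.
#' @export
pooled_deltas <- function(static_records) {
  if (nrow(static_records) < 2) {
    stop("no valid one-minute pairs in static-tag records")
  }
  rec <- static_records
  rec$minute <- floor_minute(rec$timestamp)
  rec <- rec[order(rec$tag_id, rec$receiver_id, rec$minute), ]
  grp <- paste(rec$tag_id, rec$receiver_id)
  same <- grp[-1] == grp[-length(grp)]
  dt <- diff(as.numeric(rec$minute))
  ok <- same & dt == 60
  if (!any(ok)) {
    stop("no valid one-minute pairs in static-tag records")
  }
  abs(diff(rec$signal_dbm))[ok]
}

#' Activity threshold from pooled static-tag deltas
#'
#' The upper `q` quantile (default 99%) of the pooled one-minute |delta|
#' distribution of motionless reference tags estimates the maximum signal
#' variation of an inactive bird; signal changes above it are attributed to
#' movement.  Quantiles use linear interpolation between order statistics
#' (type 7), fixed for reproducibility.
#'
#' @param deltas numeric vector of pooled |delta| values (dB), e.g. from
#'   [pooled_deltas()].
#' @param q upper quantile, default 0.99.
#' @return Threshold in dB.
#' @export
activity_threshold <- function(deltas, q = 0.99) {
  if (length(deltas) == 0) {
    stop("cannot estimate activity threshold from empty delta vector")
  }
  unname(stats::quantile(deltas, q, type = 7, names = FALSE))
}

#' Minimum-signal threshold from white-noise quantiles
#'
#' Per noise group (by convention one receiver-day), computes the `q`
#' quantile (default 95%) of recorded noise, then returns the mean of those
#' quantiles plus a margin (default 4 dB).  Signals weaker than this are
#' indistinguishable from noise and classified unknown.
#'
#' @param noise_groups list of numeric vectors of noise_dbm values, one per
#'   group; or a single numeric vector (one group).
#' @param q per-group quantile, default 0.95.
#' @param margin dB margin added to the mean quantile, default 4.
#' @return Threshold in dBm.
#' @export
#' @examples
#' min_signal_threshold(list(-132, -130))  # -131 + 4 = -127
min_signal_threshold <- function(noise_groups, q = 0.95, margin = 4.0) {
  if (is.numeric(noise_groups)) {
    noise_groups <- list(noise_groups)
  }
  noise_groups <- noise_groups[lengths(noise_groups) > 0]
  if (length(noise_groups) == 0) {
    stop("no noise groups supplied")
  }
  qs <- vapply(noise_groups, function(g) {
    stats::quantile(g, q, type = 7, names = FALSE)
  }, numeric(1))
  mean(qs) + margin
}

#' Group noise values per receiver-day
#'
#' Helper building the grouping convention used by
#' [min_signal_threshold()]: one group per (receiver, local calendar day).
#'
#' @param records signal-record tibble.
#' @param tz_offset_hours site local-time offset (default +2).
#' @return Named list of numeric noise vectors.
#' @export
group_noise_by_receiver_day <- function(records, tz_offset_hours = 2) {
  key <- paste(records$receiver_id,
               local_date(records$timestamp, tz_offset_hours))
  split(records$noise_dbm, key)
}

#' Full calibration from static-tag records
#'
#' Runs the calibration experiment analysis: the activity threshold from
#' pooled static-tag |delta| values and the minimum-signal threshold from
#' receiver-day noise quantiles.  The gap minimum and noise ceiling are not
#' estimated from data; they keep their configured values.
#'
#' @param static_records signal-record tibble from static reference tags.
#' @param base `cal_thresholds` supplying the non-estimated fields and the
#'   calibration parameters (quantiles, margin).
#' @param tz_offset_hours site local-time offset for noise grouping.
#' @return A `cal_thresholds` with `activity_delta_db` and `min_signal_dbm`
#'   replaced by their estimates.
#' @export
calibrate_thresholds <- function(static_records, base = default_thresholds(),
                                 tz_offset_hours = 2) {
  act <- activity_threshold(pooled_deltas(static_records),
                            q = base$quantile_activity)
  msig <- min_signal_threshold(
    group_noise_by_receiver_day(static_records, tz_offset_hours),
    q = base$quantile_noise, margin = base$noise_margin_db
  )
  cal_thresholds(
    activity_delta_db = act,
    min_signal_dbm = msig,
    noise_ceiling_dbm = base$noise_ceiling_dbm,
    min_gap_db = base$min_gap_db,
    quantile_activity = base$quantile_activity,
    quantile_noise = base$quantile_noise,
    noise_margin_db = base$noise_margin_db
  )
}
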