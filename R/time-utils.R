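#' Internal time helpers
#'
#' All timestamps inside the package are POSIXct in UTC.  "Local" civil time
#' at the study site is UTC plus a constant configurable offset
#' (`tz_offset_hours`, default +2, the site's summer offset); local calendar
#' days run midnight-to-midnight in that offset.
#'
#' @name time-utils
#' @keywords internal
NULL

#' Floor a timestamp to its whole minute
#'
#' A record belongs to the minute bin `floor(timestamp)`; nominal one-minute
#' cadence drift of a few seconds is thereby tolerated.
#'
#' @param t POSIXct vector.
#' @return POSIXct vector floored to whole minutes (UTC).
#' @keywords internal
floor_minute <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

#' Local calendar date of an instant
#'
#' @param t POSIXct (UTC).
#' @param tz_offset_hours numeric UTC offset of site local time.
#' @return Date vector.
#' @keywords internal
local_date <- function(t, tz_offset_hours = 2) {
  as.Date(t + tz_offset_hours * 3600, tz = "UTC")
}

#' Local time-of-day in decimal hours
#' @inheritParams local_date
#' @return numeric hours in [0, 24).
#' @keywords internal
local_hour <- function(t, tz_offset_hours = 2) {
  x <- as.numeric(t + tz_offset_hours * 3600) %% 86400
  x / 3600
}

#' Local midnight at the end of the local day containing `t`
#' @inheritParams local_date
#' @return POSIXct (UTC) of the next local midnight strictly after `t`.
#' @keywords internal
next_local_midnight <- function(t, tz_offset_hours = 2) {
  shifted <- as.numeric(t) + tz_offset_hours * 3600
  mid <- (floor(shifted / 86400) + 1) * 86400 - tz_offset_hours * 3600
  as.POSIXct(mid, origin = "1970-01-01", tz = "UTC")
}

utc_time <- function(x) {
  as.POSIXct(x, tz = "UTC")
}
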