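#' Read an ARU signal log
#'
#' Parses the delimited-text dialect written by the receiver post-processing:
#' a CSV with header `timestamp,tag_id,signal_dbm,noise_dbm,receiver_id`,
#' ISO-8601 timestamps with explicit UTC offset, "." decimal separator.
#' Records are returned sorted by (tag, receiver, timestamp); duplicate rows
#' for the same (tag, receiver, minute) are collapsed to the last occurrence
#' with a warning.
#'
#' @param source path or connection to the CSV.
#' @return A tibble with columns `timestamp` (POSIXct, UTC), `tag_id`,
#'   `signal_dbm`, `noise_dbm`, `receiver_id`.  Empty file (header only or
#'   zero bytes) yields a zero-row tibble.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("timestamp,tag_id,signal_dbm,noise_dbm,receiver_id",
#'              "2015-10-14T18:02:00+02:00,tag07,-95.2,-141.0,ARU1"), f)
#' read_aru_log(f)
read_aru_log <- function(source) {
  cols <- c("timestamp", "tag_id", "signal_dbm", "noise_dbm", "receiver_id")
  lines <- readLines(source, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(lines))) {
    return(empty_aru_log())
  }
  header <- strsplit(trimws(lines[[1]]), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), cols)) {
    stop("ARU log header must be '", paste(cols, collapse = ","),
         "', got '", lines[[1]], "'")
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    return(empty_aru_log())
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 5)) {
    bad <- which(nf != 5)[1]
    stop("malformed row at line ", bad + 1L, ": expected 5 fields, got ",
         nf[bad])
  }
  m <- matrix(trimws(unlist(parts)), ncol = 5, byrow = TRUE)
  ts <- lubridate::ymd_hms(m[, 1], tz = "UTC", quiet = TRUE)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop("unparseable timestamp at line ", bad + 1L, ": '", m[bad, 1], "'")
  }
  sig <- suppressWarnings(as.numeric(m[, 3]))
  noi <- suppressWarnings(as.numeric(m[, 4]))
  if (anyNA(sig) || !all(is.finite(sig))) {
    bad <- which(is.na(sig) | !is.finite(sig))[1]
    stop("malformed signal_dbm at line ", bad + 1L, ": '", m[bad, 3], "'")
  }
  if (anyNA(noi) || !all(is.finite(noi))) {
    bad <- which(is.na(noi) | !is.finite(noi))[1]
    stop("malformed noise_dbm at line ", bad + 1L, ": '", m[bad, 4], "'")
  }
  rec <- tibble::tibble(
    timestamp   = ts,
    tag_id      = m[, 2],
    signal_dbm  = sig,
    noise_dbm   = noi,
    receiver_id = m[, 5]
  )
  rec <- rec[order(rec$tag_id, rec$receiver_id, rec$timestamp), ]
  key <- paste(rec$tag_id, rec$receiver_id, as.numeric(floor_minute(rec$timestamp)))
  dup <- duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate (tag, receiver, minute) row(s) collapsed ",
            "to the last occurrence")
    rec <- rec[!dup, ]
  }
  rec
}

empty_aru_log <- function() {
  tibble::tibble(
    timestamp   = as.POSIXct(character(), tz = "UTC"),
    tag_id      = character(),
    signal_dbm  = double(),
    noise_dbm   = double(),
    receiver_id = character()
  )
}

#' Write an ARU signal log
#'
#' Inverse of [read_aru_log()]; timestamps are written as ISO-8601 UTC
#' (`+00:00` offset).
#'
#' @param records tibble of signal records.
#' @param sink path or connection.
#' @return `sink`, invisibly.
#' @export
write_aru_log <- function(records, sink) {
  ts <- format(records$timestamp, "%Y-%m-%dT%H:%M:%S+00:00", tz = "UTC")
  out <- paste(ts, records$tag_id, format_num(records$signal_dbm),
               format_num(records$noise_dbm), records$receiver_id, sep = ",")
  writeLines(c("timestamp,tag_id,signal_dbm,noise_dbm,receiver_id", out), sink)
  invisible(sink)
}

format_num <- function(x) {
  formatC(x, format = "f", digits = 4, drop0trailing = TRUE)
}

#' Select the best receiver for one tag-minute
#'
#' When several receivers hear the same tag in the same minute, the record
#' with the strongest (maximum) signal is kept.  This maximises detection
#' probability and is deterministic; ties break towards the
#' lexicographically first receiver id.
#'
#' @param records signal-record tibble (any number of tags/receivers).
#' @param minute POSIXct instant; the minute bin is `floor(minute)`.
#' @param tag_id tag to look up.
#' @return A one-row tibble, or `NULL` if no receiver heard the tag that
#'   minute.
#' @export
select_best_receiver <- function(records, minute, tag_id) {
  bin <- floor_minute(minute)
  sel <- records[records$tag_id == tag_id &
                   floor_minute(records$timestamp) == bin, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(NULL)
  }
  sel <- sel[order(-sel$signal_dbm, sel$receiver_id), ]
  sel[1, ]
}

#' Collapse a multi-receiver log to one record per tag-minute
#'
#' Vectorised version of [select_best_receiver()] over a whole log: for each
#' (tag, minute) keeps the strongest-signal record.  The result is the input
#' expected by [classify_series()].
#'
#' @param records signal-record tibble.
#' @return tibble with one row per (tag_id, minute), `timestamp` floored to
#'   the whole minute, sorted by tag then time.
#' @export
collapse_receivers <- function(records) {
  if (nrow(records) == 0) {
    return(empty_aru_log())
  }
  rec <- records
  rec$timestamp <- floor_minute(rec$timestamp)
  rec <- rec[order(rec$tag_id, rec$timestamp, -rec$signal_dbm, rec$receiver_id), ]
  tag_idx <- match(rec$tag_id, unique(rec$tag_id))
  key <- (tag_idx - 1) * 2^33 + round(as.numeric(rec$timestamp) / 60)
  rec[!duplicated(key), ]
}

#' Construct an activity series
#'
#' One ternary state (`"active"`, `"inactive"`, `"unknown"`) per minute for
#' one tag, gap-free: any minute without data is stored as `"unknown"`.
#'
#' @param tag_id tag identifier.
#' @param start POSIXct start instant (floored to the whole minute, UTC).
#' @param states character vector of per-minute states.
#' @return An object of class `activity_series`.
#' @export
activity_series <- function(tag_id, start, states) {
  stopifnot(is.character(states))
  bad <- setdiff(unique(states), c("active", "inactive", "unknown"))
  if (length(bad) > 0) {
    stop("invalid activity state(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(tag_id = tag_id, start = floor_minute(utc_time(start)), states = states),
    class = "activity_series"
  )
}

#' @export
length.activity_series <- function(x) length(x$states)

#' @export
print.activity_series <- function(x, ...) {
  tab <- table(factor(x$states, c("active", "inactive", "unknown")))
  cat("<activity_series> tag ", x$tag_id, ", ", length(x$states),
      " minutes from ", format(x$start, "%Y-%m-%d %H:%M UTC"), "\n",
      "  active ", tab[["active"]], " | inactive ", tab[["inactive"]],
      " | unknown ", tab[["unknown"]], "\n", sep = "")
  invisible(x)
}

#' Per-minute timestamps of an activity series
#' @param series an `activity_series`.
#' @return POSIXct vector, one instant per state.
#' @export
series_timestamps <- function(series) {
  series$start + 60 * (seq_along(series$states) - 1L)
}

#' @export
as_tibble.activity_series <- function(x, ...) {
  tibble::tibble(timestamp = series_timestamps(x), state = x$states)
}

#' Write an activity series as CSV
#'
#' Dialect: header `timestamp,state`, ISO-8601 UTC timestamps, state one of
#' active/inactive/unknown.  Round-trips losslessly through
#' [read_activity_csv()].
#'
#' @param series an `activity_series`.
#' @param sink path or connection.
#' @return `sink`, invisibly.
#' @export
write_activity_csv <- function(series, sink) {
  ts <- format(series_timestamps(series), "%Y-%m-%dT%H:%M:%S+00:00", tz = "UTC")
  writeLines(c("timestamp,state", paste(ts, series$states, sep = ",")), sink)
  invisible(sink)
}

#' Read an activity series CSV
#'
#' @param source path or connection to a file written by
#'   [write_activity_csv()].
#' @param tag_id tag identifier to attach (the dialect does not store it).
#' @return An `activity_series`.
#' @export
read_activity_csv <- function(source, tag_id = "unknown-tag") {
  lines <- readLines(source, warn = FALSE)
  if (length(lines) == 0 || !identical(trimws(lines[[1]]), "timestamp,state")) {
    stop("activity CSV must start with header 'timestamp,state'")
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    stop("activity CSV has no data rows; a series must span at least 1 minute")
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("malformed activity CSV row at line ",
         which(lengths(parts) != 2)[1] + 1L)
  }
  m <- matrix(trimws(unlist(parts)), ncol = 2, byrow = TRUE)
  ts <- lubridate::ymd_hms(m[, 1], tz = "UTC", quiet = TRUE)
  if (anyNA(ts)) {
    stop("unparseable timestamp at line ", which(is.na(ts))[1] + 1L)
  }
  activity_series(tag_id, ts[1], m[, 2])
}

#' Bird metadata table
#'
#' @param bird_id character ids (unique).
#' @param status `"migrant"` or `"resident"` (fixed per bird-year).
#' @param sex `"M"`, `"F"` or `"unknown"`.
#' @param age `"adult"`, `"juvenile"` or `"unknown"`.
#' @param year integer study year.
#' @return tibble of metadata.
#' @export
bird_meta <- function(bird_id, status, sex = "unknown", age = "unknown",
                      year = 2015L) {
  stopifnot(!anyDuplicated(paste(bird_id, year)))
  stopifnot(all(status %in% c("migrant", "resident")))
  stopifnot(all(sex %in% c("M", "F", "unknown")))
  stopifnot(all(age %in% c("adult", "juvenile", "unknown")))
  tibble::tibble(
    bird_id = as.character(bird_id),
    status = status,
    sex = rep_len(sex, length(bird_id)),
    age = rep_len(age, length(bird_id)),
    year = as.integer(rep_len(year, length(bird_id)))
  )
}
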