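#' Geometric solar altitude
#'
#' Low-precision solar ephemeris (NOAA/Meeus class: geometric mean longitude,
#' equation of center, apparent longitude, corrected obliquity, equation of
#' time), accurate to well under 0.1 degrees for contemporary dates -- ample
#' for minute-level civil-twilight work.  No atmospheric refraction is
#' applied: civil twilight is defined geometrically at -6 degrees.
#'
#' @param time POSIXct instant(s), UTC.
#' @param latitude,longitude site coordinates in decimal degrees
#'   (east/north positive).
#' @return Solar altitude(s) in degrees above the horizon.
#' @export
#' @examples
#' solar_altitude(as.POSIXct("2015-10-14 12:00:00", tz = "UTC"), 47.783, 9.033)
solar_altitude <- function(time, latitude, longitude) {
  stopifnot(abs(latitude) <= 90)
  deg2rad <- pi / 180
  t <- as.numeric(utc_time(time))
  jd <- t / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525

  L0 <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  M  <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  e  <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  Mr <- M * deg2rad
  C  <- sin(Mr) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
        sin(2 * Mr) * (0.019993 - 0.000101 * jc) +
        sin(3 * Mr) * 0.000289
  true_long <- L0 + C
  omega <- (125.04 - 1934.136 * jc) * deg2rad
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega)

  eps0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  eps  <- (eps0 + 0.00256 * cos(omega)) * deg2rad

  decl <- asin(sin(eps) * sin(app_long * deg2rad))

  y <- tan(eps / 2)^2
  L0r <- L0 * deg2rad
  eqtime <- 4 / deg2rad * (
    y * sin(2 * L0r) - 2 * e * sin(Mr) + 4 * e * y * sin(Mr) * cos(2 * L0r) -
      0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * Mr)
  )

  minutes_utc <- (t %% 86400) / 60
  tst <- (minutes_utc + eqtime + 4 * longitude) %% 1440
  ha <- (tst / 4 - 180) * deg2rad

  lat_r <- latitude * deg2rad
  alt <- asin(sin(lat_r) * sin(decl) + cos(lat_r) * cos(decl) * cos(ha))
  alt / deg2rad
}

#' Civil dawn and dusk for one date
#'
#' Finds the morning ascending and evening descending crossings of solar
#' altitude = -6 degrees (the geometric centre of the sun 6 degrees below
#' the horizon) within the local calendar day, by scanning a 1-minute grid
#' and refining each bracket by bisection to better than 1 second.
#'
#' @param date a `Date` (local calendar day at the site).
#' @param latitude,longitude site coordinates, decimal degrees.
#' @param tz_offset_hours constant UTC offset of site local time (default +2).
#' @return A one-row tibble: `date`, `civil_dawn`, `civil_dusk` (POSIXct UTC,
#'   `NA` when the sun never crosses -6 degrees), and `polar` -- `"none"`,
#'   `"day"` (sun always above -6, no twilight) or `"night"` (always below).
#' @export
civil_twilight <- function(date, latitude, longitude, tz_offset_hours = 2) {
  date <- as.Date(date)
  day_start <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") -
    tz_offset_hours * 3600
  grid <- day_start + 60 * (0:1440)
  alt <- solar_altitude(grid, latitude, longitude) + 6

  refine <- function(lo, hi) {
    f_lo <- solar_altitude(lo, latitude, longitude) + 6
    while (as.numeric(hi) - as.numeric(lo) > 0.5) {
      mid <- lo + (as.numeric(hi) - as.numeric(lo)) / 2
      f_mid <- solar_altitude(mid, latitude, longitude) + 6
      if (sign(f_mid) == sign(f_lo)) {
        lo <- mid
        f_lo <- f_mid
      } else {
        hi <- mid
      }
    }
    lo + (as.numeric(hi) - as.numeric(lo)) / 2
  }

  cross <- which(diff(sign(alt)) != 0)
  dawn <- dusk <- as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC")
  for (i in cross) {
    t_ref <- refine(grid[i], grid[i + 1])
    if (alt[i] < 0 && alt[i + 1] >= 0) {
      dawn <- t_ref  # ascending
    } else if (alt[i] >= 0 && alt[i + 1] < 0) {
      dusk <- t_ref  # descending
    }
  }
  polar <- "none"
  if (length(cross) == 0) {
    polar <- if (alt[1] > 0) "day" else "night"
  }
  tibble::tibble(date = date, civil_dawn = dawn, civil_dusk = dusk,
                 polar = polar)
}

#' Twilight table over a date range
#'
#' @param from,to first and last local calendar dates (inclusive).
#' @inheritParams civil_twilight
#' @return tibble with one row per date (see [civil_twilight()]).
#' @export
twilight_table <- function(from, to, latitude, longitude, tz_offset_hours = 2) {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  out <- dplyr::bind_rows(lapply(dates, civil_twilight,
                                 latitude = latitude, longitude = longitude,
                                 tz_offset_hours = tz_offset_hours))
  attr(out, "latitude") <- latitude
  attr(out, "longitude") <- longitude
  attr(out, "tz_offset_hours") <- tz_offset_hours
  out
}

#' Label instants as day or night
#'
#' Daytime is the interval `[civil_dawn, civil_dusk)` of the local date;
#' everything else is night, attributed to the night beginning at the most
#' recent dusk.
#'
#' @param time POSIXct vector (UTC).
#' @param twilight twilight table covering the surrounding dates
#'   (see [twilight_table()]).
#' @return Character vector, `"day"` or `"night"`.
#' @export
label_daynight <- function(time, twilight) {
  tz_off <- attr(twilight, "tz_offset_hours")
  if (is.null(tz_off)) tz_off <- 2
  d <- local_date(time, tz_off)
  idx <- match(d, twilight$date)
  if (anyNA(idx)) {
    stop("twilight table does not cover date(s): ",
         paste(unique(d[is.na(idx)]), collapse = ", "))
  }
  dawn <- twilight$civil_dawn[idx]
  dusk <- twilight$civil_dusk[idx]
  ifelse(!is.na(dawn) & !is.na(dusk) & time >= dawn & time < dusk,
         "day", "night")
}
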