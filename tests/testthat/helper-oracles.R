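# Independent oracles used by the tests.  These deliberately do NOT share
# code with the package.

# brute-force sort-and-interpolate quantile (linear interpolation between
# order statistics, the type-7 convention), written from the definition
brute_quantile <- function(x, q) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Spencer (1971) Fourier-series solar position: a different published
# derivation (truncated Fourier fit of declination and equation of time)
# from the package's NOAA/Meeus-class ephemeris.
spencer_altitude <- function(time, lat, lon) {
  t <- as.numeric(time)
  doy <- as.POSIXlt(time, tz = "UTC")$yday
  frac_h <- (t %% 86400) / 3600
  g <- 2 * pi * (doy + (frac_h - 12) / 24) / 365
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eot <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                     0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  tst <- (frac_h * 60 + eot + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * pi / 180
  latr <- lat * pi / 180
  asin(sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)) * 180 / pi
}

# civil dawn/dusk (UTC epoch seconds) from the Spencer oracle by linear
# interpolation on a 1-minute grid over the UTC day
spencer_twilight <- function(date, lat, lon) {
  t0 <- as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = "UTC"))
  grid <- t0 + 60 * (0:1440)
  a <- spencer_altitude(as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
                        lat, lon) + 6
  cr <- which(diff(sign(a)) != 0)
  dawn <- dusk <- NA_real_
  for (i in cr) {
    tm <- grid[i] + 60 * a[i] / (a[i] - a[i + 1])
    if (a[i] < 0) dawn <- tm else dusk <- tm
  }
  c(dawn = dawn, dusk = dusk)
}
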