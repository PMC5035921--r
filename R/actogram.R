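#' Double-plotted actogram
#'
#' Classic chronobiology rendering: one row per day, each row showing day d
#' followed by day d+1 (48 h), so rhythms crossing midnight read
#' continuously.  Active minutes are drawn as marks coloured by day (red)
#' and night (blue); unknown minutes are blank; a detected departure is
#' marked with an asterisk.  Both the ggplot and the numeric matrix behind
#' it are returned, so the figure is a pure function of the matrix.
#'
#' @param series an [activity_series()] spanning at least 2 local days.
#' @param twilight twilight table covering the series dates.
#' @param departure optional departure-event tibble (asterisk position).
#' @param tz_offset_hours site local-time offset (default +2).
#' @return list: `plot` (ggplot), `matrix` (days-1 rows x 2880 minute
#'   columns; 1 = active, 0 = inactive, NA = unknown), `days` (Date row
#'   labels).
#' @export
render_actogram <- function(series, twilight, departure = NULL,
                            tz_offset_hours = 2) {
  ts <- series_timestamps(series)
  d <- local_date(ts, tz_offset_hours)
  days <- sort(unique(d))
  if (length(days) < 2) {
    stop("actogram needs at least 2 days of data")
  }
  minute_of_day <- function(t) {
    as.integer((as.numeric(t + tz_offset_hours * 3600) %% 86400) / 60) + 1L
  }
  val <- ifelse(series$states == "active", 1,
                ifelse(series$states == "inactive", 0, NA))
  # per-day 1440 vectors
  day_mat <- matrix(NA_real_, length(days), 1440)
  idx <- cbind(match(d, days), minute_of_day(ts))
  day_mat[idx] <- val
  n_rows <- length(days) - 1L
  mat <- cbind(day_mat[seq_len(n_rows), , drop = FALSE],
               day_mat[1L + seq_len(n_rows), , drop = FALSE])

  labels <- label_daynight(ts, twilight)
  lab_mat <- matrix(NA_character_, length(days), 1440)
  lab_mat[idx] <- labels
  lab2 <- cbind(lab_mat[seq_len(n_rows), , drop = FALSE],
                lab_mat[1L + seq_len(n_rows), , drop = FALSE])

  pts <- which(mat == 1, arr.ind = TRUE)
  plot_df <- tibble::tibble(
    day = pts[, 1],
    hour = (pts[, 2] - 1) / 60,
    daynight = lab2[pts]
  )
  p <- ggplot2::ggplot(plot_df, ggplot2::aes(x = hour, y = day)) +
    ggplot2::geom_tile(ggplot2::aes(fill = daynight),
                       width = 1 / 60, height = 0.8) +
    ggplot2::scale_fill_manual(values = c(day = "red", night = "blue")) +
    ggplot2::scale_y_reverse(breaks = seq_len(n_rows),
                             labels = format(days[seq_len(n_rows)], "%b %d")) +
    ggplot2::scale_x_continuous(breaks = seq(0, 48, 6)) +
    ggplot2::labs(x = "hour (double-plotted, 48 h)", y = NULL,
                  title = paste("Actogram", series$tag_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(departure)) {
    dep_day <- local_date(departure$departure_time, tz_offset_hours)
    row <- match(dep_day, days)
    hr <- local_hour(departure$departure_time, tz_offset_hours)
    if (!is.na(row)) {
      row_plot <- min(row, n_rows)
      hr_plot <- if (row > n_rows) hr + 24 else hr
      p <- p + ggplot2::annotate("text", x = hr_plot, y = row_plot,
                                 label = "*", size = 8, vjust = 0.3)
    }
  }
  list(plot = p, matrix = mat, days = days[seq_len(n_rows)])
}

#' Group mean activity per half-hour across the aligned window
#'
#' Mean and standard error of percent activity per half-hour time-of-day
#' slot per group, with night shading and dashed lines spanning the
#' min--max of computed dawn and dusk over the window.
#'
#' @param budgets aligned budget tibble carrying `status` (or another
#'   grouping column named by `group`), `tod_hours`, counts.
#' @param twilight twilight table over the study window (for the dashed
#'   twilight-variation lines).
#' @param group name of the grouping column (default `"status"`).
#' @param tz_offset_hours site local-time offset (default +2).
#' @return list: `plot` (ggplot), `data` (tibble of plotted values),
#'   `twilight_range` (min/max dawn and dusk local hours).
#' @export
plot_aligned_means <- function(budgets, twilight, group = "status",
                               tz_offset_hours = 2) {
  b <- budgets[!is.na(budgets$proportion_active), , drop = FALSE]
  b$grp <- b[[group]]
  dat <- dplyr::summarise(
    dplyr::group_by(b, grp, tod_hours),
    mean_pct = 100 * mean(proportion_active),
    se_pct = 100 * stats::sd(proportion_active) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop"
  )
  dat$se_pct[is.na(dat$se_pct)] <- 0
  tw <- twilight[!is.na(twilight$civil_dawn), ]
  dawn_h <- local_hour(tw$civil_dawn, tz_offset_hours)
  dusk_h <- local_hour(tw$civil_dusk, tz_offset_hours)
  rng <- tibble::tibble(
    what = c("dawn_min", "dawn_max", "dusk_min", "dusk_max"),
    hour = c(min(dawn_h), max(dawn_h), min(dusk_h), max(dusk_h))
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(tod_hours, mean_pct,
                                         colour = grp, group = grp)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = mean(dawn_h),
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey30") +
    ggplot2::annotate("rect", xmin = mean(dusk_h), xmax = Inf,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey30") +
    ggplot2::geom_vline(xintercept = rng$hour, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean_pct - se_pct,
                                      ymax = mean_pct + se_pct, fill = grp),
                         alpha = 0.3, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time of day (h)", y = "mean activity (%)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  list(plot = p, data = dat, twilight_range = rng)
}
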