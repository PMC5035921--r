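# small builders for hand-made fixtures

# one tag, one receiver, one record per minute with the given signals
make_records <- function(signals, start = "2015-10-14 18:00:00",
                         noise = -141, tag = "tag01", receiver = "ARU1") {
  n <- length(signals)
  tibble::tibble(
    timestamp = as.POSIXct(start, tz = "UTC") + 60 * (seq_len(n) - 1),
    tag_id = tag,
    signal_dbm = signals,
    noise_dbm = rep_len(noise, n),
    receiver_id = receiver
  )
}

# a small, fast config for pipeline-level tests (single October window)
small_cfg <- function(..., seed = 1) {
  sim_config(
    n_migrants = 2, n_residents = 2, n_departure_events = 2,
    start_date = "2015-09-25", end_date = "2015-10-12",
    departure_date_range = c("2015-10-03", "2015-10-09"),
    storm_rate = 0, seed = seed, ...
  )
}

# site twilight table for tests needing day/night labels
site_twilight <- function(from = "2015-10-01", to = "2015-10-20") {
  twilight_table(from, to, 47.783, 9.033, 2)
}
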