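# shared fixtures: tiny hand-built event streams and diaries

event_df <- function(start, duration_s, activity, steps = 0,
                     participant_id = "P001") {
  data.frame(participant_id = participant_id,
             start = as.POSIXct(start, format = "%Y-%m-%dT%H:%M:%S",
                                tz = "UTC"),
             duration_s = duration_s, activity = activity,
             steps = steps, stringsAsFactors = FALSE)
}

diary_row <- function(date = "2021-03-01", wake = "07:00", onset = "23:00",
                      nap_start = "", nap_end = "",
                      class_start = "", class_end = "",
                      participant_id = "P001") {
  data.frame(participant_id = participant_id, date = date,
             wake_hhmm = wake, sleep_onset_hhmm = onset,
             nap_start_hhmm = nap_start, nap_end_hhmm = nap_end,
             class_start_hhmm = class_start, class_end_hhmm = class_end,
             stringsAsFactors = FALSE)
}

# a full wear day: lying in bed 23:00-07:00, sitting/standing filling the rest
full_day_events <- function(date = "2021-03-01", extra = NULL) {
  iso <- function(h, m = 0) sprintf("%sT%02d:%02d:00", date, h, m)
  ev <- rbind(
    event_df(iso(0), 7 * 3600, "lying"),
    event_df(iso(7), 9 * 3600, "sitting"),
    event_df(iso(16), 4 * 3600, "standing"),
    event_df(iso(20), 3 * 3600, "sitting"),
    event_df(iso(23), 3600, "lying"))
  ev
}

random_compositions <- function(n, D = 4, names = parts_4[seq_len(D)]) {
  m <- matrix(exp(stats::rnorm(n * D, 0, 1)), nrow = n)
  colnames(m) <- names
  closure(m, 1)
}
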