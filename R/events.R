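#' Read an activity-monitor events file
#'
#' Expected columns: `participant_id`, `start_iso8601`
#' (`YYYY-MM-DDTHH:MM:SS`, local clock, no DST adjustment), `duration_s`,
#' `activity` (one of lying / sitting / standing / stepping), `steps`.
#' Events spanning midnight are retained intact; they are split later by
#' [segment_day()]. Overlapping events for the same participant and
#' unknown activity labels are hard errors.
#'
#' @param path CSV file path.
#' @return data.frame of events with `start` parsed to POSIXct (UTC).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "start_iso8601", "duration_s", "activity", "steps")
  if (!all(need %in% names(df)))
    stop("events file ", path, " lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  start <- as.POSIXct(df$start_iso8601, format = "%Y-%m-%dT%H:%M:%S",
                      tz = "UTC")
  bad <- which(is.na(start) | is.na(df$duration_s) | df$duration_s <= 0 |
                 is.na(df$steps) | df$steps < 0)
  if (length(bad))
    stop("malformed event row(s) in ", path, " at line(s) ",
         paste(bad + 1L, collapse = ", "))
  unknown <- which(!df$activity %in% c("lying", "sitting", "standing", "stepping"))
  if (length(unknown))
    stop("unknown activity label(s) '",
         paste(unique(df$activity[unknown]), collapse = "', '"),
         "' in ", path, " at line(s) ", paste(unknown + 1L, collapse = ", "))
  nonstep <- df$activity != "stepping" & df$steps > 0
  if (any(nonstep))
    stop("non-stepping event(s) with steps > 0 in ", path, " at line(s) ",
         paste(which(nonstep) + 1L, collapse = ", "))
  out <- data.frame(participant_id = df$participant_id, start = start,
                    duration_s = as.numeric(df$duration_s),
                    activity = df$activity, steps = as.numeric(df$steps),
                    stringsAsFactors = FALSE)
  check_no_overlap(out, path)
  out
}

check_no_overlap <- function(events, where = "events") {
  for (pid in unique(events$participant_id)) {
    e <- events[events$participant_id == pid, ]
    o <- order(e$start)
    ends <- as.numeric(e$start[o]) + e$duration_s[o]
    starts <- as.numeric(e$start[o])
    k <- which(starts[-1] < ends[-length(ends)] - 1e-9)
    if (length(k)) {
      rows <- rownames(e)[o][c(k[1], k[1] + 1L)]
      stop("overlapping events for participant ", pid, " in ", where,
           ": rows ", rows[1], " and ", rows[2])
    }
  }
  invisible(events)
}

#' Read a time-use diary file
#'
#' Columns: `participant_id`, `date`, `wake_hhmm`, `sleep_onset_hhmm`,
#' optional `nap_start_hhmm`/`nap_end_hhmm` and
#' `class_start_hhmm`/`class_end_hhmm`. `sleep_onset_hhmm` is the time the
#' participant fell asleep on the night following `date`; "24:00" means
#' no in-bed time before the next midnight.
#'
#' @param path CSV file path.
#' @return data.frame, one row per participant-day.
#' @export
read_diary <- function(path) {
  if (!file.exists(path)) stop("diary file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("participant_id", "date", "wake_hhmm", "sleep_onset_hhmm")
  if (!all(need %in% names(df)))
    stop("diary file ", path, " lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  for (opt in c("nap_start_hhmm", "nap_end_hhmm",
                "class_start_hhmm", "class_end_hhmm"))
    if (!opt %in% names(df)) df[[opt]] <- ""
  bad <- which(is.na(hhmm_to_sec(df$wake_hhmm)) |
                 is.na(hhmm_to_sec(df$sleep_onset_hhmm)))
  if (length(bad))
    stop("malformed diary row(s) in ", path, " at line(s) ",
         paste(bad + 1L, collapse = ", "))
  df
}

#' Read a condition schedule file
#'
#' Columns: `participant_id`, `date`, `condition`
#' (onsite / online / weekend).
#' @param path CSV file path.
#' @return data.frame mapping participant-days to conditions.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("participant_id", "date", "condition")
  if (!all(need %in% names(df)))
    stop("schedule file ", path, " lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(!df$condition %in% c("onsite", "online", "weekend"))
  if (length(bad))
    stop("unknown condition(s) in ", path, " at line(s) ",
         paste(bad + 1L, collapse = ", "))
  df
}

#' Clip an event stream to one midnight-to-midnight day
#'
#' Events crossing a midnight are split proportionally: duration and steps
#' are prorated by the fraction of the event inside the day. Gaps are
#' non-wear. Total clipped duration plus gap time is always 1440 min.
#'
#' @param events data.frame as from [read_events()] (one participant).
#' @param date the calendar day (`Date` or string).
#' @return data.frame with `start_s` (seconds since the day's midnight),
#'   `duration_s`, `activity`, `steps` (possibly fractional after
#'   proration), clipped to `[0, 86400)`.
#' @export
segment_day <- function(events, date) {
  d0 <- as.numeric(as.POSIXct(as.Date(date), tz = "UTC"))
  t0 <- as.numeric(events$start) - d0
  t1 <- t0 + events$duration_s
  keep <- t1 > 0 & t0 < 86400
  e <- events[keep, , drop = FALSE]
  t0 <- t0[keep]; t1 <- t1[keep]
  c0 <- pmax(t0, 0); c1 <- pmin(t1, 86400)
  frac <- (c1 - c0) / (t1 - t0)
  out <- data.frame(start_s = c0, duration_s = c1 - c0,
                    activity = e$activity, steps = e$steps * frac,
                    stringsAsFactors = FALSE)
  out[order(out$start_s), , drop = FALSE]
}

in_bed_intervals <- function(diary_day) {
  wake <- hhmm_to_sec(diary_day$wake_hhmm)
  onset <- hhmm_to_sec(diary_day$sleep_onset_hhmm)
  rbind(if (wake > 0) c(0, wake),
        if (onset < 86400) c(onset, 86400))
}

nap_interval <- function(diary_day) {
  if (is.na(diary_day$nap_start_hhmm) || !nzchar(diary_day$nap_start_hhmm))
    return(NULL)
  c(hhmm_to_sec(diary_day$nap_start_hhmm),
    hhmm_to_sec(diary_day$nap_end_hhmm))
}

class_interval <- function(diary_day) {
  if (is.null(diary_day$class_start_hhmm) ||
      is.na(diary_day$class_start_hhmm) ||
      !nzchar(diary_day$class_start_hhmm))
    return(NULL)
  c(hhmm_to_sec(diary_day$class_start_hhmm),
    hhmm_to_sec(diary_day$class_end_hhmm))
}

# minutes of events of given activities overlapping a set of intervals
overlap_min <- function(day_events, intervals, activities = NULL) {
  if (is.null(intervals) || !nrow(day_events)) return(0)
  if (!is.matrix(intervals)) intervals <- matrix(intervals, ncol = 2)
  e <- day_events
  if (!is.null(activities)) e <- e[e$activity %in% activities, , drop = FALSE]
  if (!nrow(e)) return(0)
  tot <- 0
  for (k in seq_len(nrow(intervals))) {
    lo <- pmax(e$start_s, intervals[k, 1])
    hi <- pmin(e$start_s + e$duration_s, intervals[k, 2])
    tot <- tot + sum(pmax(hi - lo, 0))
  }
  tot / 60
}

#' Split a day's worn time into sleep and waking behaviours
#'
#' The diary in-bed window (sleep onset to wake, split at midnight onto
#' adjacent dates) defines primary lying. Sleep SL = primary-lying
#' minutes + self-reported nap minutes; sedentary SB = sitting +
#' secondary-lying (lying outside bed) minutes - nap minutes, floored at
#' 0 with a warning when the diary over-reports naps. A nap interval that
#' overlaps no sitting/lying event is flagged as a diary inconsistency
#' but still applied.
#'
#' @param day_events clipped day events from [segment_day()].
#' @param diary_day one diary row for the same date.
#' @return list with minutes: `SL`, `SB`, `primary_lying`,
#'   `secondary_lying`, `sitting`, `nap`.
#' @export
label_sleep <- function(day_events, diary_day) {
  bed <- in_bed_intervals(diary_day)
  nap <- nap_interval(diary_day)
  lying_tot <- overlap_min(day_events, c(0, 86400), "lying")
  primary <- overlap_min(day_events, bed, "lying")
  secondary <- lying_tot - primary
  sitting <- overlap_min(day_events, c(0, 86400), "sitting")
  nap_min <- 0
  if (!is.null(nap)) {
    nap_min <- (nap[2] - nap[1]) / 60
    if (overlap_min(day_events, nap, c("sitting", "lying")) < 1e-9)
      warning("nap interval ", sec_to_hhmm(nap[1]), "-", sec_to_hhmm(nap[2]),
              " overlaps no sitting/lying event; applying it anyway")
  }
  sb <- sitting + secondary - nap_min
  if (sb < 0) {
    warning("nap minutes exceed sitting + secondary lying; flooring SB at 0")
    sb <- 0
  }
  list(SL = primary + nap_min, SB = sb, primary_lying = primary,
       secondary_lying = secondary, sitting = sitting, nap = nap_min)
}

#' Count MVPA minutes by the step-cadence method
#'
#' The day is partitioned into clock-aligned 1-min epochs; each stepping
#' event's steps are prorated uniformly over the epochs it overlaps; an
#' epoch with >= 100 steps is an MVPA minute. Stepping time in
#' sub-threshold epochs is left to be absorbed by the LPA residual.
#'
#' @param day_events clipped day events from [segment_day()].
#' @param window optional `c(start_s, end_s)`; when given, only epochs
#'   whose midpoint falls inside the window are counted.
#' @return number of MVPA epochs (minutes).
#' @export
compute_mvpa <- function(day_events, window = NULL) {
  steps <- epoch_steps(day_events)
  hot <- which(steps >= 100 - 1e-9)
  if (!is.null(window)) {
    mid <- (hot - 1) * 60 + 30
    hot <- hot[mid >= window[1] & mid < window[2]]
  }
  length(hot)
}

# per-epoch prorated step counts (length-1440 vector)
epoch_steps <- function(day_events) {
  out <- numeric(1440)
  st <- day_events[day_events$activity == "stepping" & day_events$steps > 0, ,
                   drop = FALSE]
  for (k in seq_len(nrow(st))) {
    t0 <- st$start_s[k]; t1 <- t0 + st$duration_s[k]
    e0 <- floor(t0 / 60); e1 <- min(floor((t1 - 1e-9) / 60), 1439)
    for (e in e0:e1) {
      ov <- min(t1, (e + 1) * 60) - max(t0, e * 60)
      out[e + 1L] <- out[e + 1L] + st$steps[k] * ov / (t1 - t0)
    }
  }
  out
}

#' Summarise one participant-day into behaviour minutes
#'
#' Computes the 4-part day (SL, SB, LPA, MVPA) plus non-wear: SL and SB
#' from [label_sleep()], MVPA from [compute_mvpa()], and LPA as the
#' residual of wear time (1440 - SL - SB - MVPA - nonwear). A day is
#' valid when non-wear is at most 240 min (4 h) and a diary row exists.
#' For valid days with a class window, the lecture/leisure domain split
#' of [partition_domains()] is appended.
#'
#' @param events all events for one participant.
#' @param diary_day diary row for the date, or `NULL` if none.
#' @param date calendar day.
#' @param condition schedule condition for the day.
#' @return one-row data.frame (a daily summary).
#' @export
summarize_day <- function(events, diary_day, date, condition = NA_character_) {
  day_ev <- segment_day(events, date)
  nonwear <- 1440 - sum(day_ev$duration_s) / 60
  base <- data.frame(
    participant_id = if (nrow(events)) events$participant_id[1] else NA_character_,
    date = as.character(as.Date(date)), condition = condition,
    SL = 0, SB = 0, LPA = 0, MVPA = 0, nonwear = nonwear,
    valid = FALSE, reason = "", SL6 = NA_real_, SB_leisure = NA_real_,
    LPA_leisure = NA_real_, MVPA_leisure = NA_real_,
    SB_lecture = NA_real_, PA_lecture = NA_real_,
    stringsAsFactors = FALSE)
  if (is.null(diary_day)) {
    base$reason <- "no diary"
    return(base)
  }
  sl <- label_sleep(day_ev, diary_day)
  mvpa <- compute_mvpa(day_ev)
  lpa <- 1440 - sl$SL - sl$SB - mvpa - nonwear
  if (lpa < 0) lpa <- 0
  base$SL <- sl$SL; base$SB <- sl$SB; base$LPA <- lpa; base$MVPA <- mvpa
  if (nonwear > 240) {
    base$reason <- "nonwear > 240 min"
    return(base)
  }
  base$valid <- TRUE
  cls <- class_interval(diary_day)
  if (!is.null(cls)) {
    dom <- partition_domains(day_ev, diary_day,
                             totals = c(SL = base$SL, SB = base$SB,
                                        LPA = base$LPA, MVPA = base$MVPA),
                             nonwear = nonwear)
    for (nm in names(dom)) base[[nm]] <- dom[[nm]]
  }
  base
}

#' Partition a valid schooling day into lecture and leisure domains
#'
#' Behaviours inside the diary class window form the lecture domain;
#' lecture LPA and MVPA are amalgamated into a single PA part (zero
#' lecture MVPA is a true zero). The remainder of the waking day is
#' leisure, obtained by deducting the lecture (raw) minutes from the day
#' totals. Non-wear overlapping a domain is redistributed by
#' proportionally rescaling that domain's parts to the domain's window
#' length (factor `window / (window - nonwear_in_window)`), so
#' SL + lecture parts + leisure parts = 1440 exactly.
#'
#' @param day_events clipped day events.
#' @param diary_day diary row with a class window.
#' @param totals named day totals (SL, SB, LPA, MVPA minutes).
#' @param nonwear whole-day non-wear minutes.
#' @return named list: `SL6`, `SB_leisure`, `LPA_leisure`,
#'   `MVPA_leisure`, `SB_lecture`, `PA_lecture` (minutes).
#' @export
partition_domains <- function(day_events, diary_day, totals, nonwear = 0) {
  cls <- class_interval(diary_day)
  if (is.null(cls)) stop("partition_domains: diary day has no class window")
  bed <- in_bed_intervals(diary_day)
  if (!is.null(bed)) {
    ov <- overlap_min(data.frame(start_s = cls[1],
                                 duration_s = cls[2] - cls[1],
                                 activity = "x", steps = 0,
                                 stringsAsFactors = FALSE), bed, NULL)
    if (ov > 1e-9)
      stop("class window overlaps the diary sleep window on ",
           diary_day$date)
  }
  L <- (cls[2] - cls[1]) / 60
  nap <- nap_interval(diary_day)
  nap_in_cls <- if (is.null(nap))
    0 else max(0, (min(nap[2], cls[2]) - max(nap[1], cls[1]))) / 60

  sb_lect_raw <- overlap_min(day_events, cls, c("sitting", "lying")) - nap_in_cls
  mvpa_lect <- compute_mvpa(day_events, window = cls)
  lpa_lect_raw <- max(0, overlap_min(day_events, cls,
                                     c("standing", "stepping")) - mvpa_lect)
  worn_lect <- overlap_min(day_events, cls, NULL)
  nw_lect <- L - worn_lect
  lect_scale <- if (worn_lect - nap_in_cls > 0)
    (L - nap_in_cls) / (worn_lect - nap_in_cls) else 1

  sb_leis_raw <- totals[["SB"]] - sb_lect_raw
  lpa_leis_raw <- totals[["LPA"]] - lpa_lect_raw
  mvpa_leis <- totals[["MVPA"]] - mvpa_lect
  leis_len <- 1440 - totals[["SL"]] - L
  leis_raw_sum <- sb_leis_raw + lpa_leis_raw + mvpa_leis
  leis_scale <- if (leis_raw_sum > 0) leis_len / leis_raw_sum else 1

  list(SL6 = totals[["SL"]],
       SB_leisure = sb_leis_raw * leis_scale,
       LPA_leisure = lpa_leis_raw * leis_scale,
       MVPA_leisure = mvpa_leis * leis_scale,
       SB_lecture = sb_lect_raw * lect_scale,
       PA_lecture = (lpa_lect_raw + mvpa_lect) * lect_scale)
}

#' Process a cohort of event streams into daily summaries
#'
#' Runs [summarize_day()] for every participant-day in the schedule.
#'
#' @param events combined events data.frame (all participants).
#' @param diary diary data.frame from [read_diary()].
#' @param schedule schedule data.frame from [read_schedule()].
#' @return data.frame of daily summaries.
#' @export
process_cohort <- function(events, diary, schedule) {
  check_no_overlap(events)
  out <- vector("list", nrow(schedule))
  for (r in seq_len(nrow(schedule))) {
    pid <- schedule$participant_id[r]
    date <- schedule$date[r]
    ev <- events[events$participant_id == pid, , drop = FALSE]
    dd <- diary[diary$participant_id == pid & diary$date == date, ,
                drop = FALSE]
    drow <- if (nrow(dd)) dd[1, ] else NULL
    s <- summarize_day(ev, drow, date, schedule$condition[r])
    s$participant_id <- pid
    out[[r]] <- s
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the valid-day and 3+3 inclusion rules, aggregate to participant level
#'
#' Weekend days are dropped; a participant must contribute at least
#' `min_valid` valid weekdays in each condition. For each included
#' participant and condition the arithmetic mean of each behaviour's
#' minutes over valid days is closed to 1440 (4-part and, where the
#' domain split exists, 6-part). Compositional (geometric-mean)
#' aggregation across days is available as an option.
#'
#' @param summaries daily summaries from [process_cohort()].
#' @param min_valid minimum valid days per condition (default 3).
#' @param aggregate `"arithmetic"` (default) or `"compositional"`.
#' @return list with `table` (one row per participant-condition, closed
#'   4-part and 6-part compositions) and `excluded`
#'   (participant, reason).
#' @export
include_participants <- function(summaries, min_valid = 3,
                                 aggregate = c("arithmetic", "compositional")) {
  aggregate <- match.arg(aggregate)
  s <- summaries
  wd <- !format(as.Date(s$date), "%u") %in% c("6", "7") &
    s$condition %in% c("onsite", "online")
  s <- s[wd & s$valid, , drop = FALSE]
  excluded <- data.frame(participant_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  rows <- list()
  for (pid in unique(summaries$participant_id)) {
    sp <- s[s$participant_id == pid, , drop = FALSE]
    n_on <- sum(sp$condition == "onsite")
    n_ol <- sum(sp$condition == "online")
    if (n_on < min_valid || n_ol < min_valid) {
      excluded <- rbind(excluded, data.frame(
        participant_id = pid,
        reason = sprintf("valid days onsite=%d online=%d < %d",
                         n_on, n_ol, min_valid),
        stringsAsFactors = FALSE))
      next
    }
    for (cond in c("onsite", "online")) {
      sc <- sp[sp$condition == cond, , drop = FALSE]
      agg <- function(cols, total) {
        m <- as.matrix(sc[, cols, drop = FALSE])
        if (anyNA(m)) return(rep(NA_real_, length(cols)))
        v <- if (aggregate == "arithmetic") colMeans(m)
             else if (all(m > 0)) compositional_mean(m, total) else colMeans(m)
        closure(v, total)
      }
      p4 <- agg(parts_4, 1440)
      p6 <- agg(parts_6, 1440)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid, condition = cond,
        as.list(stats::setNames(p4, parts_4)),
        as.list(stats::setNames(p6, parts_6)),
        n_days = nrow(sc), stringsAsFactors = FALSE)
    }
  }
  if (nrow(excluded))
    for (k in seq_len(nrow(excluded)))
      message("excluding ", excluded$participant_id[k], ": ",
              excluded$reason[k])
  tbl <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(tbl)) warning("no participants meet the inclusion rule")
  list(table = tbl, excluded = excluded)
}
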