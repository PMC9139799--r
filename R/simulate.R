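#' Simulation configuration for a paired two-condition cohort
#'
#' Defines the study conditions the simulator emulates: each participant is
#' observed on `days_per_condition` weekdays under onsite schooling and the
#' same number under online schooling. Daily 4-part compositions are
#' logistic-normal on the ilr scale: a participant-level random effect
#' (shared across conditions, giving the paired structure) plus day-level
#' noise around the condition mean.
#'
#' Dispersion defaults are on the 3 pivot (ilr) coordinates in the
#' canonical order SL, SB, LPA, MVPA; the third coordinate (LPA vs MVPA)
#' is given the largest spread because day-to-day MVPA is the most
#' variable behaviour.
#'
#' @param n_participants number of participants (>= 2).
#' @param days_per_condition valid weekdays per condition (default 5).
#' @param mean_onsite,mean_online named 4-part mean compositions in
#'   min/day (closed to 1440 internally); defaults from
#'   [default_condition_means()].
#' @param between_sd,within_sd non-negative 3-vectors of standard
#'   deviations on the ilr scale for the participant random effect and
#'   the day-level noise.
#' @param lecture_window character `c(start, end)` "HH:MM" school-class
#'   window on schooling weekdays (default 08:00-14:00, both conditions).
#' @param nap_probability per-day probability of a 30-min afternoon nap
#'   (default 0).
#' @param lecture_sitting_bias multiplicative preference for placing
#'   sitting bouts inside the lecture window (default 1.2; 1 = no bias).
#' @param seed integer RNG seed; the whole cohort is deterministic given it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_participants,
                       days_per_condition = 5,
                       mean_onsite = default_condition_means()$onsite,
                       mean_online = default_condition_means()$online,
                       between_sd = c(0.25, 0.20, 0.45),
                       within_sd = c(0.35, 0.30, 0.60),
                       lecture_window = c("08:00", "14:00"),
                       nap_probability = 0,
                       lecture_sitting_bias = 1.2,
                       seed = 1L) {
  for (nm in c("mean_onsite", "mean_online")) {
    m <- get(nm)
    if (is.null(names(m)) || !setequal(names(m), parts_4))
      stop(nm, " must be a named 4-part vector with parts ",
           paste(parts_4, collapse = ", "))
    m <- m[parts_4]
    bad <- names(m)[m <= 0]
    if (length(bad))
      stop(nm, ": non-positive mean for part(s) ",
           paste(bad, collapse = ", "))
    assign(nm, closure(m, 1440))
  }
  stopifnot(n_participants >= 2, days_per_condition >= 1,
            length(between_sd) == 3, length(within_sd) == 3,
            all(between_sd >= 0), all(within_sd >= 0),
            nap_probability >= 0, nap_probability <= 1,
            lecture_sitting_bias > 0)
  lw <- hhmm_to_sec(lecture_window)
  stopifnot(length(lw) == 2, lw[1] < lw[2])
  structure(list(
    n_participants = as.integer(n_participants),
    days_per_condition = as.integer(days_per_condition),
    mean_onsite = mean_onsite, mean_online = mean_online,
    between_sd = between_sd, within_sd = within_sd,
    lecture_window = lecture_window,
    nap_probability = nap_probability,
    lecture_sitting_bias = lecture_sitting_bias,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# consecutive study weekdays starting Monday 2021-03-01 (onsite block)
# then the following weeks (online block); weekends are skipped
study_dates <- function(days_per_condition) {
  start <- as.Date("2021-03-01")
  all_days <- seq(start, by = "day", length.out = 7 * ceiling(days_per_condition / 5) * 2 + 14)
  wk <- all_days[!format(all_days, "%u") %in% c("6", "7")]
  list(onsite = wk[seq_len(days_per_condition)],
       online = wk[days_per_condition + seq_len(days_per_condition)])
}

#' Simulate paired per-participant-day 4-part compositions
#'
#' Generative model: with `z_c = ilr(condition mean)` (pivot coordinates,
#' SL leading), participant i has latent mean `z_c + u_i`, where
#' `u_i ~ N(0, diag(between_sd^2))` is shared across conditions; each day
#' adds `N(0, diag(within_sd^2))` noise; the inverse ilr maps back to the
#' simplex and rescales to 1440 min. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `days` (data.frame: participant_id, condition, date,
#'   SL, SB, LPA, MVPA) and `truth` (latent participant means per
#'   condition and the true condition effect on the ilr scale,
#'   `ilr(online mean) - ilr(onsite mean)`).
#' @export
simulate_compositions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  z_on <- pivot_ilr(config$mean_onsite, leading = "SL")
  z_ol <- pivot_ilr(config$mean_online, leading = "SL")
  dates <- study_dates(config$days_per_condition)
  n <- config$n_participants
  d <- config$days_per_condition
  pid <- sprintf("P%03d", seq_len(n))

  u <- matrix(stats::rnorm(n * 3, 0, rep(config$between_sd, each = n)),
              nrow = n)
  rows <- vector("list", n * 2L)
  lat_on <- lat_ol <- matrix(NA_real_, n, 4,
                             dimnames = list(pid, parts_4))
  for (i in seq_len(n)) {
    zi_on <- z_on + u[i, ]
    zi_ol <- z_ol + u[i, ]
    lat_on[i, ] <- inverse_pivot_ilr(zi_on, parts_4, 1440)
    lat_ol[i, ] <- inverse_pivot_ilr(zi_ol, parts_4, 1440)
    per_cond <- function(zi, cond, dts) {
      eps <- matrix(stats::rnorm(d * 3, 0, rep(config$within_sd, each = d)),
                    nrow = d)
      comp <- t(vapply(seq_len(d), function(j)
        inverse_pivot_ilr(zi + eps[j, ], parts_4, 1440), numeric(4)))
      data.frame(participant_id = pid[i], condition = cond,
                 date = dts, comp, stringsAsFactors = FALSE)
    }
    rows[[2L * i - 1L]] <- per_cond(zi_on, "onsite", dates$onsite)
    rows[[2L * i]]      <- per_cond(zi_ol, "online", dates$online)
  }
  days <- do.call(rbind, rows)
  rownames(days) <- NULL
  list(days = days,
       truth = list(
         ilr_effect = as.numeric(z_ol - z_on),
         participant_means_onsite = lat_on,
         participant_means_online = lat_ol,
         mean_onsite = config$mean_onsite,
         mean_online = config$mean_online,
         seed = config$seed))
}

# interval helpers: intervals are 2-col matrices [start, end), seconds
int_len <- function(iv) if (!length(iv)) 0 else sum(iv[, 2] - iv[, 1])

int_subtract <- function(iv, cut) {
  # subtract one [a,b) from a list of disjoint sorted intervals
  out <- list()
  for (k in seq_len(nrow(iv))) {
    a <- iv[k, 1]; b <- iv[k, 2]
    lo <- max(a, cut[1]); hi <- min(b, cut[2])
    if (lo >= hi) { out[[length(out) + 1L]] <- c(a, b); next }
    if (a < lo) out[[length(out) + 1L]] <- c(a, lo)
    if (hi < b) out[[length(out) + 1L]] <- c(hi, b)
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, out)
}

#' Simulate one day's activity-monitor event stream
#'
#' Emits a midnight-to-midnight event sequence (lying during the diary
#' in-bed window, sitting during naps, and sitting / standing / stepping
#' bouts elsewhere) whose per-behaviour totals, when processed back with
#' the same diary, recover `day_composition` within +/- 1 min per part.
#' MVPA minutes are realised as clock-minute-aligned stepping epochs at
#' 120 steps/min (>= the 100 steps/min cadence threshold); residual slow
#' stepping runs at 40 steps/min so no other epoch can reach threshold.
#' Bout lengths are exponential; events have 1-s resolution.
#'
#' @param day_composition named 4-part vector of minutes (sum <= 1440).
#' @param diary one-row data.frame (or list) with `date`, `wake_hhmm`,
#'   `sleep_onset_hhmm`, optional `nap_start_hhmm`/`nap_end_hhmm`,
#'   optional `class_start_hhmm`/`class_end_hhmm`. In-bed minutes within
#'   the day plus nap minutes must equal SL within 1 min.
#' @param seed integer seed (deterministic output).
#' @param participant_id id copied into the records.
#' @param lecture_sitting_bias preference for sitting inside the class
#'   window (see [sim_config()]).
#' @return data.frame of events: `participant_id`, `start` (POSIXct UTC),
#'   `duration_s`, `activity`, `steps`.
#' @export
simulate_event_stream <- function(day_composition, diary, seed,
                                  participant_id = "P001",
                                  lecture_sitting_bias = 2) {
  comp <- day_composition[parts_4]
  if (any(is.na(comp)) || any(comp < 0) || sum(comp) > 1440 + 1e-9)
    stop("day_composition must be non-negative SL/SB/LPA/MVPA minutes summing to <= 1440")
  date <- as.Date(diary$date)
  wake <- hhmm_to_sec(diary$wake_hhmm)
  onset <- hhmm_to_sec(diary$sleep_onset_hhmm)
  if (is.na(wake) || is.na(onset))
    stop("diary must supply wake and sleep-onset times")
  if (wake > onset) stop("diary sleep window covers the whole day")
  nap <- NULL
  if (!is.null(diary$nap_start_hhmm) && !is.na(diary$nap_start_hhmm) &&
      nzchar(diary$nap_start_hhmm)) {
    nap <- c(hhmm_to_sec(diary$nap_start_hhmm), hhmm_to_sec(diary$nap_end_hhmm))
    if (nap[1] < wake || nap[2] > onset || nap[1] >= nap[2])
      stop("nap interval must lie within waking hours")
  }
  lect <- NULL
  if (!is.null(diary$class_start_hhmm) && !is.na(diary$class_start_hhmm) &&
      nzchar(diary$class_start_hhmm)) {
    lect <- c(hhmm_to_sec(diary$class_start_hhmm),
              hhmm_to_sec(diary$class_end_hhmm))
  }
  in_bed <- rbind(if (wake > 0) c(0, wake),
                  if (onset < 86400) c(onset, 86400))
  nap_min <- if (is.null(nap)) 0 else (nap[2] - nap[1]) / 60
  bed_min <- int_len(in_bed) / 60
  if (abs(bed_min + nap_min - comp[["SL"]]) > 1)
    stop("diary in-bed window (", bed_min, " min) + naps (", nap_min,
         " min) inconsistent with SL = ", round(comp[["SL"]], 2), " min")

  set.seed(seed)
  ev <- list()
  add <- function(start, dur, act, steps = 0) {
    ev[[length(ev) + 1L]] <<- data.frame(
      start_s = start, duration_s = dur, activity = act, steps = steps)
  }
  if (!is.null(in_bed)) for (k in seq_len(nrow(in_bed)))
    add(in_bed[k, 1], in_bed[k, 2] - in_bed[k, 1], "lying")
  if (!is.null(nap)) add(nap[1], nap[2] - nap[1], "sitting")

  waking <- matrix(c(wake, onset), ncol = 2)
  if (!is.null(nap)) waking <- int_subtract(waking, nap)

  # MVPA: whole clock minutes fully inside waking time
  m <- round(comp[["MVPA"]])
  cand <- integer(0)
  for (k in seq_len(nrow(waking))) {
    lo <- ceiling(waking[k, 1] / 60); hi <- floor(waking[k, 2] / 60) - 1L
    if (hi >= lo) cand <- c(cand, lo:hi)
  }
  if (m > length(cand))
    stop("not enough waking clock minutes for ", m, " MVPA epochs")
  mv <- sort(if (m > 0) cand[sample.int(length(cand), m)] else integer(0))
  if (m > 0) {
    runs <- split(mv, cumsum(c(1, diff(mv) != 1)))
    for (r in runs) {
      add(r[1] * 60, 60 * length(r), "stepping", steps = 120L * length(r))
      waking <- int_subtract(waking, c(r[1] * 60, (r[1] + length(r)) * 60))
    }
  }

  # fill the rest with sitting / standing / slow stepping bouts
  targets <- c(sit = comp[["SB"]] * 60,
               stand = 0.7 * (int_len(waking) - comp[["SB"]] * 60),
               substep = 0.3 * (int_len(waking) - comp[["SB"]] * 60))
  if (any(targets < -60))
    stop("composition inconsistent with waking time available")
  targets <- pmax(targets, 0)
  mean_bout <- c(sit = 900, stand = 240, substep = 120)
  acts <- c(sit = "sitting", stand = "standing", substep = "stepping")
  for (k in seq_len(nrow(waking))) {
    pos <- waking[k, 1]; end <- waking[k, 2]
    in_lect <- !is.null(lect) && pos >= lect[1] && pos < lect[2]
    while (pos < end - 1e-9) {
      w <- targets
      if (in_lect) w["sit"] <- w["sit"] * lecture_sitting_bias
      if (sum(w) <= 0) { a <- "stand"; dur <- end - pos } else {
        a <- sample(names(w), 1, prob = w / sum(w))
        dur <- max(30, round(stats::rexp(1, 1 / mean_bout[a])))
        dur <- min(dur, end - pos, if (targets[a] > 0) targets[a] else dur)
      }
      dur <- round(dur)
      if (dur < 1) dur <- 1
      if (pos + dur > end) dur <- end - pos
      steps <- if (a == "substep") as.integer(round(dur / 60 * 40)) else 0L
      add(pos, dur, acts[[if (a %in% names(acts)) a else "stand"]], steps)
      targets[a] <- max(0, targets[a] - dur)
      pos <- pos + dur
      in_lect <- !is.null(lect) && pos >= lect[1] && pos < lect[2]
    }
  }
  out <- do.call(rbind, ev)
  out <- out[order(out$start_s), , drop = FALSE]
  data.frame(participant_id = participant_id,
             start = as.POSIXct(date, tz = "UTC") + out$start_s,
             duration_s = out$duration_s,
             activity = out$activity,
             steps = as.integer(out$steps),
             stringsAsFactors = FALSE)
}

#' Simulate a full cohort: compositions, diaries, schedules, event streams
#'
#' Draws daily compositions with [simulate_compositions()], constructs a
#' consistent time-use diary for every participant-day (wake at 07:00 or
#' earlier for short sleepers, sleep onset placed so the in-bed window
#' within the midnight-to-midnight day matches the day's SL; classes
#' during `lecture_window` on every schooling weekday; optional 30-min
#' 16:00 naps), and emits the matching event stream for each day.
#'
#' @param config a [sim_config()].
#' @return list of class `cohort`: `events`, `diary`, `schedule`
#'   (data.frames in the documented CSV dialects), `days` (true daily
#'   compositions), `truth`, `config`.
#' @export
simulate_cohort <- function(config) {
  sim <- simulate_compositions(config)
  days <- sim$days
  set.seed(config$seed + 500009L)
  nap_draw <- stats::runif(nrow(days)) < config$nap_probability
  diary <- vector("list", nrow(days))
  events <- vector("list", nrow(days))
  for (r in seq_len(nrow(days))) {
    sl <- days$SL[r]
    nap_min <- if (nap_draw[r] && sl > 450) 30 else 0
    sl_bed <- sl - nap_min
    morning <- min(sl_bed, 420)          # wake at 07:00 unless short sleep
    evening <- sl_bed - morning
    wake_s <- round(morning * 60)
    onset_s <- round(86400 - evening * 60)
    drow <- data.frame(
      participant_id = days$participant_id[r],
      date = as.character(days$date[r]),
      wake_hhmm = sec_to_hhmm(wake_s),
      sleep_onset_hhmm = sec_to_hhmm(onset_s),
      nap_start_hhmm = if (nap_min > 0) "16:00" else "",
      nap_end_hhmm = if (nap_min > 0) "16:30" else "",
      class_start_hhmm = config$lecture_window[1],
      class_end_hhmm = config$lecture_window[2],
      stringsAsFactors = FALSE)
    diary[[r]] <- drow
    ev_seed <- (config$seed + 7919L * r) %% 2147483647L
    events[[r]] <- simulate_event_stream(
      unlist(days[r, parts_4]), drow, seed = ev_seed,
      participant_id = days$participant_id[r],
      lecture_sitting_bias = config$lecture_sitting_bias)
  }
  schedule <- data.frame(participant_id = days$participant_id,
                         date = as.character(days$date),
                         condition = days$condition,
                         stringsAsFactors = FALSE)
  structure(list(events = do.call(rbind, events),
                 diary = do.call(rbind, diary),
                 schedule = schedule,
                 days = days, truth = sim$truth, config = config),
            class = "cohort")
}

#' Write / read a cohort as plain-text files
#'
#' Writes one events CSV per participant (`events_<id>.csv`), a shared
#' `diary.csv`, `schedule.csv` and `ground_truth.json`. Re-reading with
#' [read_cohort()] reproduces the in-memory records.
#'
#' @param dirpath output directory (created if missing).
#' @param cohort a [simulate_cohort()] result.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return `dirpath`, invisibly.
#' @export
write_cohort <- function(dirpath, cohort, overwrite = FALSE) {
  if (dir.exists(dirpath) && length(dir(dirpath)) && !overwrite)
    stop("directory ", dirpath, " is not empty; use overwrite = TRUE")
  dir.create(dirpath, showWarnings = FALSE, recursive = TRUE)
  ev <- cohort$events
  ev_out <- data.frame(participant_id = ev$participant_id,
                       start_iso8601 = format(ev$start, "%Y-%m-%dT%H:%M:%S",
                                              tz = "UTC"),
                       duration_s = ev$duration_s,
                       activity = ev$activity, steps = ev$steps)
  for (pid in unique(ev_out$participant_id)) {
    utils::write.csv(ev_out[ev_out$participant_id == pid, ],
                     file.path(dirpath, paste0("events_", pid, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  if (!nrow(ev))
    utils::write.csv(ev_out, file.path(dirpath, "events_empty.csv"),
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$diary, file.path(dirpath, "diary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$schedule, file.path(dirpath, "schedule.csv"),
                   row.names = FALSE, quote = FALSE)
  tr <- cohort$truth
  tr$participant_means_onsite <- as.data.frame(tr$participant_means_onsite)
  tr$participant_means_online <- as.data.frame(tr$participant_means_online)
  tr$mean_onsite <- as.list(tr$mean_onsite)
  tr$mean_online <- as.list(tr$mean_online)
  jsonlite::write_json(tr, file.path(dirpath, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dirpath)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dirpath) {
  ev_files <- sort(dir(dirpath, pattern = "^events_.*\\.csv$",
                       full.names = TRUE))
  events <- do.call(rbind, lapply(ev_files, read_events))
  diary <- read_diary(file.path(dirpath, "diary.csv"))
  schedule <- read_schedule(file.path(dirpath, "schedule.csv"))
  truth <- jsonlite::read_json(file.path(dirpath, "ground_truth.json"),
                               simplifyVector = TRUE)
  list(events = events, diary = diary, schedule = schedule, truth = truth)
}

#' Aggregate simulated daily compositions to participant-condition means
#'
#' Arithmetic mean of each behaviour's minutes over a participant's days
#' within each condition, closed to 1440 — the same aggregation
#' [include_participants()] applies to processed daily summaries, for use
#' when working directly with simulated compositions.
#'
#' @param days `days` data.frame from [simulate_compositions()].
#' @return data.frame with `participant_id`, `condition` and the closed
#'   4-part composition.
#' @export
aggregate_days <- function(days) {
  key <- interaction(days$participant_id, days$condition, drop = TRUE)
  rows <- lapply(split(days, key), function(d) {
    data.frame(participant_id = d$participant_id[1],
               condition = d$condition[1],
               as.list(closure(colMeans(d[, parts_4]), 1440)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
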