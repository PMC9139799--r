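# Event stream processing: readers, day segmentation, sleep labelling,
# cadence-based MVPA, daily summaries, domain split, inclusion rules

test_that("readers parse well-formed files and reject structural problems", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("participant_id,start_iso8601,duration_s,activity,steps",
               "P001,2021-03-01T08:00:00,600,sitting,0",
               "P001,2021-03-01T08:10:00,300,standing,0",
               "P001,2021-03-01T08:15:00,120,stepping,200"), f)
  ev <- read_events(f)
  expect_equal(nrow(ev), 3)
  expect_s3_class(ev$start, "POSIXct")

  writeLines(c("participant_id,start_iso8601,duration_s,activity,steps",
               "P001,2021-03-01T08:00:00,600,sitting,0",
               "P001,2021-03-01T08:05:00,600,standing,0"), f)
  expect_error(read_events(f), "overlapping events for participant P001")

  writeLines(c("participant_id,start_iso8601,duration_s,activity,steps",
               "P001,2021-03-01T08:00:00,600,jogging,0"), f)
  expect_error(read_events(f), "unknown activity")

  # an event spanning midnight is retained intact at read time
  writeLines(c("participant_id,start_iso8601,duration_s,activity,steps",
               "P001,2021-03-01T22:00:00,36000,lying,0"), f)
  expect_equal(read_events(f)$duration_s, 36000)
  unlink(f)
})

test_that("diary and schedule readers validate their dialects", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("participant_id,date,wake_hhmm,sleep_onset_hhmm",
               "P001,2021-03-01,07:00,23:00"), f)
  d <- read_diary(f)
  expect_equal(nrow(d), 1)
  expect_true(all(c("nap_start_hhmm", "class_start_hhmm") %in% names(d)))
  writeLines(c("participant_id,date,condition",
               "P001,2021-03-01,onsite", "P001,2021-03-06,weekend"), f)
  expect_equal(nrow(read_schedule(f)), 2)
  writeLines(c("participant_id,date,condition",
               "P001,2021-03-01,hybrid"), f)
  expect_error(read_schedule(f), "unknown condition")
  unlink(f)
})

test_that("segment_day splits midnight-crossing events proportionally", {
  ev <- event_df("2021-03-01T22:00:00", 10 * 3600, "lying")
  d1 <- segment_day(ev, "2021-03-01")
  d2 <- segment_day(ev, "2021-03-02")
  expect_equal(d1$duration_s / 60, 120)
  expect_equal(d2$duration_s / 60, 480)
  expect_equal(segment_day(ev, "2021-03-05")$duration_s, numeric(0))
  # steps are prorated with duration
  st <- event_df("2021-03-01T23:50:00", 1200, "stepping", steps = 100)
  expect_equal(segment_day(st, "2021-03-01")$steps, 50)
  expect_equal(segment_day(st, "2021-03-02")$steps, 50)
})

test_that("day segmentation conserves duration and steps over random streams", {
  set.seed(19)
  for (rep in 1:5) {
    n <- 40
    starts <- as.POSIXct("2021-03-01", tz = "UTC") +
      sort(sample.int(3 * 86400 - 4000, n))
    dur <- stats::rexp(n, 1 / 600) + 1
    # make non-overlapping: truncate each at the next start
    dur <- pmin(dur, c(as.numeric(diff(starts)), Inf))
    ev <- data.frame(participant_id = "P001", start = starts,
                     duration_s = dur, activity = "stepping",
                     steps = stats::rpois(n, 50), stringsAsFactors = FALSE)
    clipped <- lapply(as.Date("2021-03-01") + 0:3,
                      function(dd) segment_day(ev, dd))
    expect_equal(sum(vapply(clipped, function(x) sum(x$duration_s),
                            numeric(1))),
                 sum(ev$duration_s), tolerance = 1e-9)
    expect_equal(sum(vapply(clipped, function(x) sum(x$steps), numeric(1))),
                 sum(ev$steps), tolerance = 1e-9)
  }
})

test_that("sleep labelling follows the diary in-bed window and naps", {
  # continuous lying 23:00 -> 07:00: 60 min to onset date, 420 to wake date
  ev <- event_df("2021-03-01T23:00:00", 8 * 3600, "lying")
  d1 <- label_sleep(segment_day(ev, "2021-03-01"), diary_row())
  d2 <- label_sleep(segment_day(ev, "2021-03-02"),
                    diary_row(date = "2021-03-02"))
  expect_equal(d1$SL, 60)
  expect_equal(d2$SL, 420)

  # a 30-min nap during a sitting bout moves 30 min from SB to SL
  base_ev <- full_day_events()
  no_nap <- label_sleep(segment_day(base_ev, "2021-03-01"), diary_row())
  with_nap <- label_sleep(segment_day(base_ev, "2021-03-01"),
                          diary_row(nap_start = "14:00", nap_end = "14:30"))
  expect_equal(with_nap$SL, no_nap$SL + 30)
  expect_equal(with_nap$SB, no_nap$SB - 30)

  # nap over a standing period: flagged, still applied
  expect_warning(
    flagged <- label_sleep(segment_day(base_ev, "2021-03-01"),
                           diary_row(nap_start = "17:00", nap_end = "17:30")),
    "overlaps no sitting/lying")
  expect_equal(flagged$SL, no_nap$SL + 30)

  # lying outside the in-bed window is secondary lying (sedentary)
  ev2 <- rbind(full_day_events()[-2, ],
               event_df("2021-03-01T07:00:00", 9 * 3600, "lying"))
  lab <- label_sleep(segment_day(ev2, "2021-03-01"), diary_row())
  expect_equal(lab$secondary_lying, 540)
  expect_equal(lab$SB, no_nap$SB)
})

test_that("step-cadence MVPA counts clock epochs at >= 100 steps/min", {
  ev <- event_df("2021-03-01T10:00:00", 600, "stepping", steps = 1100)
  expect_equal(compute_mvpa(segment_day(ev, "2021-03-01")), 10)
  slow <- event_df("2021-03-01T10:00:00", 600, "stepping", steps = 900)
  expect_equal(compute_mvpa(segment_day(slow, "2021-03-01")), 0)
})

test_that("MVPA matches a brute-force per-second epoch oracle on mixed days", {
  set.seed(77)
  for (rep in 1:3) {
    n <- 30
    starts <- sort(sample.int(86400 - 600, n))
    dur <- pmin(stats::rexp(n, 1 / 180) + 10,
                c(diff(starts), 600))
    ev <- data.frame(start_s = starts, duration_s = dur,
                     activity = "stepping",
                     steps = stats::rpois(n, dur / 60 * 90),
                     stringsAsFactors = FALSE)
    # oracle: spread each event's steps uniformly over seconds, sum per epoch
    sec <- numeric(86400)
    for (k in seq_len(n)) {
      idx <- (floor(starts[k]) + 1):(floor(starts[k] + dur[k]))
      rate <- ev$steps[k] / dur[k]
      add <- rep(rate, length(idx))
      # partial first/last seconds
      add[1] <- rate * (1 - (starts[k] - floor(starts[k])))
      end_frac <- (starts[k] + dur[k]) - floor(starts[k] + dur[k])
      if (end_frac > 0) add <- c(add, rate * end_frac)
      idx <- (floor(starts[k]) + 1):(floor(starts[k]) + length(add))
      sec[idx] <- sec[idx] + add
    }
    oracle <- sum(colSums(matrix(sec, nrow = 60)) >= 100 - 1e-9)
    expect_equal(compute_mvpa(ev), oracle)
  }
})

test_that("summarize_day applies the residual identity and the 4-h validity rule", {
  # pure non-wear day
  s0 <- summarize_day(event_df("2021-03-05T08:00:00", 60, "sitting")[0, ],
                      diary_row(date = "2021-03-05"), "2021-03-05")
  expect_false(s0$valid)
  expect_equal(s0$nonwear, 1440)
  expect_equal(s0$SL + s0$SB + s0$LPA + s0$MVPA, 0)

  # day with exactly 240 min non-wear is valid; 241 is not
  mk <- function(gap_min) {
    rbind(event_df("2021-03-01T00:00:00", 7 * 3600, "lying"),
          event_df(sprintf("2021-03-01T%02d:%02d:00",
                           7 + (gap_min %/% 60), gap_min %% 60),
                   (17 * 60 - gap_min) * 60 - 3600, "sitting"),
          event_df("2021-03-01T23:00:00", 3600, "lying"))
  }
  expect_true(summarize_day(mk(240), diary_row(), "2021-03-01")$valid)
  expect_false(summarize_day(mk(241), diary_row(), "2021-03-01")$valid)

  # missing diary marks the day invalid with reason
  s <- summarize_day(full_day_events(), NULL, "2021-03-01")
  expect_false(s$valid)
  expect_match(s$reason, "no diary")

  # minute conservation of the 4 parts + nonwear
  s2 <- summarize_day(mk(100), diary_row(), "2021-03-01")
  expect_equal(s2$SL + s2$SB + s2$LPA + s2$MVPA + s2$nonwear, 1440,
               tolerance = 1e-6)
})

test_that("processing is invariant to event-file row order", {
  cfg <- sim_config(2, days_per_condition = 1, seed = 55)
  co <- simulate_cohort(cfg)
  shuffled <- co$events[sample(nrow(co$events)), ]
  a <- process_cohort(co$events, co$diary, co$schedule)
  b <- process_cohort(shuffled, co$diary, co$schedule)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("domain partition rescales non-wear and amalgamates lecture PA", {
  dr <- diary_row(class_start = "08:00", class_end = "14:00")
  # full wear, constant behaviours: conservation to 1440
  ev <- rbind(event_df("2021-03-01T00:00:00", 7 * 3600, "lying"),
              event_df("2021-03-01T07:00:00", 13 * 3600, "sitting"),
              event_df("2021-03-01T20:00:00", 3 * 3600, "standing"),
              event_df("2021-03-01T23:00:00", 3600, "lying"))
  s <- summarize_day(ev, dr, "2021-03-01")
  expect_equal(s$SL6 + s$SB_leisure + s$LPA_leisure + s$MVPA_leisure +
                 s$SB_lecture + s$PA_lecture, 1440, tolerance = 1e-6)
  expect_equal(s$SB_lecture, 360)   # whole window sitting
  expect_equal(s$PA_lecture, 0)

  # 30 min non-wear inside the 360-min window: parts scaled by 360/330
  ev_gap <- rbind(event_df("2021-03-01T00:00:00", 7 * 3600, "lying"),
                  event_df("2021-03-01T07:00:00", 3 * 3600, "sitting"),
                  # gap 10:00-10:30
                  event_df("2021-03-01T10:30:00", 9.5 * 3600, "sitting"),
                  event_df("2021-03-01T20:00:00", 3 * 3600, "standing"),
                  event_df("2021-03-01T23:00:00", 3600, "lying"))
  sg <- summarize_day(ev_gap, dr, "2021-03-01")
  expect_equal(sg$SB_lecture, 330 * 360 / 330)
  expect_equal(sg$SB_lecture + sg$PA_lecture, 360, tolerance = 1e-9)

  # lecture LPA with zero >= 100-cadence stepping: PA = LPA (true zero)
  ev_lpa <- rbind(event_df("2021-03-01T00:00:00", 7 * 3600, "lying"),
                  event_df("2021-03-01T07:00:00", 3600, "sitting"),
                  event_df("2021-03-01T08:00:00", 2 * 3600, "standing"),
                  event_df("2021-03-01T10:00:00", 13 * 3600, "sitting"),
                  event_df("2021-03-01T23:00:00", 3600, "lying"))
  sl <- summarize_day(ev_lpa, dr, "2021-03-01")
  expect_equal(sl$PA_lecture, 120)

  # class window overlapping the sleep window is an error
  expect_error(
    summarize_day(ev, diary_row(class_start = "06:00", class_end = "14:00"),
                  "2021-03-01"),
    "class window overlaps")
})

test_that("inclusion applies the 3+3 valid-weekday rule and averages correctly", {
  cfg <- sim_config(3, days_per_condition = 4, seed = 91)
  co <- simulate_cohort(cfg)
  s <- process_cohort(co$events, co$diary, co$schedule)
  # participant P003 loses onsite days -> only 2 valid onsite days remain
  drop <- which(s$participant_id == "P003" & s$condition == "onsite")[1:2]
  s$valid[drop] <- FALSE
  expect_message(inc <- include_participants(s), "excluding P003")
  expect_false("P003" %in% inc$table$participant_id)
  expect_equal(nrow(inc$table), 4)  # 2 participants x 2 conditions
  expect_equal(unname(rowSums(as.matrix(inc$table[, parts_4]))),
               rep(1440, 4), tolerance = 1e-9)

  # averaging oracle: arithmetic mean of valid-day minutes, then closure
  p1 <- s[s$participant_id == "P001" & s$condition == "onsite" & s$valid, ]
  oracle <- closure(colMeans(p1[, parts_4]), 1440)
  got <- unlist(inc$table[inc$table$participant_id == "P001" &
                            inc$table$condition == "onsite", parts_4])
  expect_equal(got, oracle, tolerance = 1e-9)

  # all days valid and identical -> mean equals any single day
  one <- s[1, ]
  rep_s <- do.call(rbind, replicate(6, one, simplify = FALSE))
  rep_s$condition <- rep(c("onsite", "online"), each = 3)
  inc2 <- include_participants(rep_s)
  expect_equal(unlist(inc2$table[1, parts_4]),
               closure(unlist(one[parts_4]), 1440), tolerance = 1e-9)
})
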