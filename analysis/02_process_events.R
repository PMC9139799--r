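#!/usr/bin/env Rscript
# Step 2: event processing.
#
# Reads the simulated event streams, diaries and schedule back from disk
# (the same readers handle real monitor exports in this dialect), clips
# each stream to midnight-to-midnight days, labels sleep from the diary,
# counts MVPA by the >= 100 steps/min cadence rule, takes LPA as the wear
# residual, applies the 4-h non-wear validity rule and the 3+3 valid
# weekday inclusion rule, and aggregates to one composition per
# participant and condition.

suppressPackageStartupMessages(library(acticomp))

cohort <- read_cohort("scratch/cohort")
summaries <- process_cohort(cohort$events, cohort$diary, cohort$schedule)
cat("Daily summaries:", nrow(summaries), "participant-days;",
    sum(summaries$valid), "valid\n")

inc <- include_participants(summaries)
cat("Included participants:",
    length(unique(inc$table$participant_id)), "of",
    length(unique(summaries$participant_id)), "\n")

dir.create("results", showWarnings = FALSE)
utils::write.csv(summaries, "scratch/daily_summaries.csv", row.names = FALSE)
utils::write.csv(inc$table, "results/participant_conditions.csv",
                 row.names = FALSE)
utils::write.csv(inc$excluded, "results/exclusions.csv", row.names = FALSE)
cat("Wrote results/participant_conditions.csv\n")
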