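#!/usr/bin/env Rscript
# Step 4: did the pipeline recover the generator's truth?
#
# Compares the estimated condition effect (mean paired ilr differences of
# the processed cohort) with the ground truth stored next to the simulated
# event files, and the estimated compositional means with the generator's
# condition means.

suppressPackageStartupMessages(library(acticomp))

truth <- jsonlite::read_json("scratch/cohort/ground_truth.json",
                             simplifyVector = TRUE)
tbl <- utils::read.csv("results/participant_conditions.csv",
                       stringsAsFactors = FALSE)

d <- paired_ilr_differences(tbl, parts_4, leading = "SL")
est <- colMeans(d)
cat("True ilr effect:     ",
    paste(sprintf("% .4f", truth$ilr_effect), collapse = " "), "\n")
cat("Estimated ilr effect:",
    paste(sprintf("% .4f", est), collapse = " "), "\n")

for (cond in c("onsite", "online")) {
  cm <- compositional_mean(tbl[tbl$condition == cond, parts_4], 1440)
  gen <- unlist(truth[[paste0("mean_", cond)]])[parts_4]
  cat(sprintf("%-6s mean (est):  %s\n", cond,
              paste(sprintf("%7.1f", cm), collapse = " ")))
  cat(sprintf("%-6s mean (true): %s\n", cond,
              paste(sprintf("%7.1f", gen), collapse = " ")))
}
cat("\n(min/day, order ", paste(parts_4, collapse = ", "), ")\n", sep = "")
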