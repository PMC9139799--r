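Package: acticomp
Title: Compositional Analysis of 24-Hour Movement Behaviours from
    Thigh-Worn Activity Monitor Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving daily sleep (SL), sedentary behaviour (SB),
    light physical activity (LPA) and moderate-to-vigorous physical activity
    (MVPA) minutes from thigh-worn inclinometer event streams combined with
    time-use diaries, and for analysing the resulting 24-hour time-use
    compositions with compositional data analysis: closure, compositional
    (geometric) means, isometric log-ratio pivot coordinates and their
    rotations, paired-condition repeated-measures MANOVA via one-sample
    Hotelling T-squared on ilr differences, pivot-coordinate post hoc paired
    t-tests with Cohen's d, and geometric-mean log-ratio bar plots. Includes
    a logistic-normal cohort simulator that emits activity-monitor event
    files, diaries and condition schedules with known ground truth, so the
    full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
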