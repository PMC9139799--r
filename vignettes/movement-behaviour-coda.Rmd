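---
title: "Compositional analysis of 24-hour movement behaviours: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of 24-hour movement behaviours: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acticomp)
```

## The problem

A day has a fixed budget: 1440 minutes divided between sleep (SL),
sedentary behaviour (SB), light physical activity (LPA) and
moderate-to-vigorous physical activity (MVPA). Minutes spent in one
behaviour are necessarily taken from the others, so the four daily totals
are perfectly collinear and carry only *relative* information. Standard
per-behaviour ANOVAs on raw minutes ignore this constraint; compositional
data analysis (CoDa) respects it by working in the Aitchison geometry of
the simplex.

`acticomp` implements a complete pipeline for paired two-condition
studies of device-measured movement behaviour — the motivating design
compares high-school students' behaviour on onsite-schooling versus
online-schooling weekdays — from thigh-worn inclinometer event streams
to the multivariate tests.

## From events to daily compositions

The monitor emits a stream of posture/stepping events (start time,
duration, activity class, step count). Processing follows the
conventions of thigh-worn-monitor time-use studies:

* **Day definition.** Midnight-to-midnight; events crossing midnight are
  split proportionally (duration and steps prorated). All intervals are
  half-open `[start, end)` in local clock time; no DST adjustment is
  applied (a documented limitation — study blocks rarely straddle a
  clock change, and a shifted hour would corrupt one day by at most
  60 min of non-wear).
* **Sleep.** Device lying time inside the diary-reported in-bed window
  (sleep onset to wake, split across adjacent dates at midnight) is
  *primary lying*; SL = primary lying + self-reported nap minutes.
  Sitting plus lying outside the in-bed window, minus nap minutes, is
  SB. A nap that overlaps no sitting/lying event is flagged as a diary
  inconsistency but still applied, and SB is floored at zero with a
  warning — diaries are self-reports and can over-state naps; refusing
  the day outright would silently bias the sample toward accurate
  diarists.
* **MVPA.** The step-cadence rule: the day is partitioned into
  clock-aligned 1-min epochs, each stepping event's steps are prorated
  uniformly over the epochs it overlaps, and an epoch with >= 100 steps
  is an MVPA minute. Clock alignment makes the count reproducible and
  independent of event-file row order; sub-threshold stepping time falls
  through to LPA.
* **LPA.** The wear-time residual, LPA = 1440 − SL − SB − MVPA −
  non-wear. Standing and slow stepping are therefore never classified
  directly.
* **Validity and inclusion.** A day is valid when non-wear <= 240 min
  (4 h). Weekends are dropped, and a participant is included only with
  at least 3 valid weekdays under *each* condition. Per participant and
  condition, daily minutes are averaged arithmetically over valid days
  and closed to 1440. Arithmetic-mean-then-closure is the field's
  convention for "usual behaviour"; a compositional (geometric-mean)
  aggregation across days is available via
  `include_participants(..., aggregate = "compositional")`. The two
  differ for skewed behaviours (MVPA most of all): the arithmetic mean
  of lognormal-ish days exceeds their geometric mean, which is visible
  in simulations as a modest upward shift of the cohort-level MVPA mean
  relative to the generator's latent median. Because the shift is common
  to both conditions it largely cancels in paired differences.
* **Whole-day closure.** The 4-part composition of a valid day with
  non-wear is closed to 1440 rather than left short. The ilr transform
  is scale-invariant, so this choice cannot affect any coordinate or
  test; it only standardises the printed minutes.

### Lecture and leisure domains

On schooling weekdays the diary records a class window (default
08:00–14:00, both conditions — online classes also have timetables).
Behaviours inside the window form the **lecture** domain. Because many
students accumulate *no* MVPA during classes — a structural (true) zero —
lecture LPA and MVPA are amalgamated into a single PA part rather than
zero-replaced. The **leisure** domain is obtained by deducting lecture
(raw) minutes from the day totals. Non-wear overlapping a domain is
redistributed by rescaling that domain's parts to its window length
(factor `window/(window − nonwear_in_window)`), after which
SL + lecture parts + leisure parts reconstitute 1440 exactly. The
resulting 6-part composition is SL, leisure SB/LPA/MVPA, lecture SB/PA.

## Compositional machinery

All log-ratio work uses **pivot coordinates**, the ilr basis whose first
coordinate contrasts one part against the geometric mean of the rest.
For a D-part composition with the leading part placed first,

$$z_k = \sqrt{\tfrac{D-k}{D-k+1}}\,
  \ln\!\frac{x_k}{\bigl(\prod_{j=k+1}^{D} x_j\bigr)^{1/(D-k)}},
  \qquad k = 1,\dots,D-1 .$$

Re-leading each part in turn ("pivot rotation") yields an interpretable
first coordinate for every behaviour; the non-leading parts keep the
canonical order SL, SB, LPA, MVPA, which is immaterial for the first
coordinate (the geometric mean is order-invariant). The transform is an
isometry — Euclidean distance between coordinate vectors equals
Aitchison distance — and scale-invariant, both verified by
property-style tests. The centre of a sample is the **compositional
mean** (closed part-wise geometric mean); its ilr image equals the
arithmetic mean of the individual ilr vectors, which is why mean first
pivot coordinates can be recomputed directly from printed compositional
means. We compute mean coordinates as the mean of per-subject
coordinates; by this identity the alternative (coordinate of the mean)
is numerically identical.

Zeros are never silently replaced: log-ratio functions reject them and
point to `amalgamate()`. An explicit multiplicative replacement
(`replace_zeros()`, delta = half the smallest positive value) exists
behind a warning for rounded zeros.

## Inference

The paired two-condition design is analysed on ilr differences
(online − onsite, one vector per participant):

* **RM MANOVA.** A repeated-measures MANOVA with two within-subject
  levels is *exactly* a one-sample Hotelling $T^2$ test on the
  differences: $T^2 = n\,\bar d^{\,\prime} S^{-1} \bar d$, Wilks
  $\Lambda = (1 + T^2/(n-1))^{-1}$,
  $F = \frac{n-p}{p(n-1)}T^2$ on $(p,\,n-p)$ df. The implementation is
  cross-checked in the tests against `anova.mlm`'s intercept test and a
  brute-force quadratic form.
* **Post hoc pivot tests.** For each behaviour, a two-sided paired
  t-test on the first pivot coordinate with that part leading, with
  Student-t 95% CI and Cohen's $d$ = mean/SD of differences
  (0.2/0.5/0.8 small/medium/large). The mean difference equals the ilr1
  gap between the two compositional means to numerical precision
  (mean-commutation identity, asserted at 1e-9).
* **Multiplicity.** No adjustment by default, matching the reporting
  convention of the motivating design; `holm = TRUE` adds Holm-adjusted
  p-values. p-values are reported at full precision. CIs use t
  quantiles; at n around 50 the difference from normal quantiles is
  negligible.
* **Degenerate inputs.** Zero-variance differences with zero mean give
  t = 0, p = 1; with nonzero mean, t is reported infinite with a
  warning; a singular difference covariance aborts the MANOVA with a
  pointer to amalgamation.

## The synthetic cohort generator

No participant-level data are distributable, so the package ships a
generator whose output exercises every pipeline stage with known truth.
Daily compositions are **logistic-normal on the ilr scale**: participant
mean = ilr(condition mean) + participant random effect (diagonal
covariance, shared across conditions — this creates the paired
structure), day = participant mean + day noise, inverse-ilr, close to
1440. This is the minimal generative model consistent with the analysis
applied to the data.

Defaults define the emulated study conditions:

* Condition means: the published onsite (431.9, 730.5, 252.5, 25.2) and
  online (468.9, 755.0, 201.5, 14.5) min/day compositional means.
* Dispersions: no subject-level variability was published, so these are
  user parameters. Defaults `between_sd = (0.25, 0.20, 0.45)` and
  `within_sd = (0.35, 0.30, 0.60)` on the SL-leading pivot scale were
  chosen once as values a time-use researcher would call realistic —
  day-to-day variability exceeding between-person variability, and the
  LPA-vs-MVPA coordinate the most variable because daily MVPA is the
  most erratic behaviour. At these values the implied day-level spread
  of MVPA spans roughly half to double a participant's median, and
  cohort effects of the published size are detected with power
  comfortably above the nominal design's.
* Events: each day's composition is realised at 1-s resolution — lying
  across the diary in-bed window, MVPA as clock-minute-aligned stepping
  epochs at 120 steps/min, remaining waking time filled with
  exponential-length sitting/standing/slow-stepping bouts (mean 15, 4
  and 2 min; slow stepping at 40 steps/min so no non-MVPA epoch can
  cross the cadence threshold). Sitting bouts are mildly favoured
  (x1.2) inside the lecture window so classroom time is more sedentary,
  as observed in classrooms. The round trip
  generator → events → processing recovers each part within 1 min/day
  (rounding MVPA to whole epochs is the binding term).
* Diaries: wake at 07:00 (earlier only for short sleepers), sleep onset
  placed so the in-bed window matches the day's SL; classes 08:00–14:00
  on every schooling weekday; naps off by default
  (`nap_probability = 0`) but exercisable.
* Schedule: one onsite week then one online week of consecutive
  weekdays starting Monday 2021-03-01.

What the generator does **not** emulate: raw accelerometry and posture
classification errors, device non-wear (worn 24 h unless events are
edited), diary misreport beyond the nap path, weekday structure within
conditions, or any lecture-specific behaviour beyond the sitting bias.
Passing tests therefore demonstrate correctness of the *pipeline
arithmetic and inference* under a faithful generative model — not
robustness to classifier noise or diary error in field data.

## Problem sizes used in the shipped checks

The test suite works at sizes chosen to make sampling error, not
runtime, the binding constraint: law-of-large-numbers checks at 500
participants; null-calibration of the pivot t-test and the MANOVA on
1000 simulated null cohorts of the study's size (n = 51, rejection rate
required in [0.035, 0.065] at alpha = 0.05); CI coverage over 200
study-sized replicates (binomial band around 0.95); sign-pattern
recovery at n = 500. The worked-example checks (pivot coordinates and
percent changes from the published compositional means, the
Wilks-to-F conversion) are deterministic desk calculations.

## Known limitations

* Sleep requires a diary; there is no algorithmic sleep detection.
* The proprietary posture classifier is out of scope — event classes
  are trusted inputs.
* Local-clock timestamps without DST handling.
* Between-subject covariates (sex, BMI, urbanicity) are not modelled;
  the analysis is strictly the paired two-condition contrast.
* The arithmetic-vs-compositional day-aggregation choice matters for
  skewed behaviours; both are provided, arithmetic is the default.
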