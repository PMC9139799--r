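#' Data behind a geometric-mean log-ratio bar plot
#'
#' The bar plot compares two compositional means part by part on the
#' log-ratio scale; bar heights are `exp(log ratio) * 100 - 100`, the
#' percent change in each part's share of the day. The plot is always
#' rendered from this table, so results can be checked without reading
#' pixels.
#'
#' @param mean_a,mean_b named compositional means (reference first).
#' @return data.frame with `part`, `log_ratio`, `pct_change`.
#' @export
make_barplot_data <- function(mean_a, mean_b) {
  logratio_change(mean_a, mean_b)
}

#' Render the geometric-mean bar plot
#'
#' @param bar_data table from [make_barplot_data()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_logratio_bars <- function(bar_data, title = "Online vs onsite schooling") {
  bar_data$part <- factor(bar_data$part, levels = bar_data$part)
  ggplot2::ggplot(bar_data,
                  ggplot2::aes(x = .data$part, y = .data$pct_change)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "% change in share of the day",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Run the full pipeline and write its artefacts
#'
#' Either simulates a cohort (when `config` is a [sim_config()]) or reads
#' events/diary/schedule files, then processes events into daily
#' summaries, applies the inclusion rules, runs the compositional
#' analysis, and writes: `daily_summaries.csv`,
#' `participant_conditions.csv`, `results.json`, `posthoc.csv`,
#' `barplot_data_4part.csv` (+ 6-part when available),
#' `logratio_barplot.pdf` and `exclusions.csv`.
#'
#' @param config a [sim_config()], or a list with paths `events`
#'   (vector of files), `diary`, `schedule`.
#' @param out_dir output directory.
#' @param holm Holm-adjust post hoc p-values.
#' @param aggregate day-to-participant aggregation, see
#'   [include_participants()].
#' @return the `coda_analysis` result, invisibly.
#' @export
run_pipeline <- function(config, out_dir, holm = FALSE,
                         aggregate = "arithmetic") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(config, "sim_config")) {
    cohort <- simulate_cohort(config)
    events <- cohort$events
    diary <- cohort$diary
    schedule <- cohort$schedule
  } else {
    stopifnot(all(c("events", "diary", "schedule") %in% names(config)))
    events <- do.call(rbind, lapply(config$events, read_events))
    diary <- read_diary(config$diary)
    schedule <- read_schedule(config$schedule)
  }
  summaries <- process_cohort(events, diary, schedule)
  utils::write.csv(summaries, file.path(out_dir, "daily_summaries.csv"),
                   row.names = FALSE)
  inc <- include_participants(summaries, aggregate = aggregate)
  utils::write.csv(inc$excluded, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  if (is.null(inc$table)) stop("no participants meet the inclusion rule")
  utils::write.csv(inc$table, file.path(out_dir, "participant_conditions.csv"),
                   row.names = FALSE)
  res <- run_full_analysis(inc$table, holm = holm)
  write_results(res, out_dir)
  invisible(res)
}

#' Write analysis results as JSON and CSV artefacts
#'
#' @param res a `coda_analysis` from [run_full_analysis()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manova_block <- function(m) if (is.null(m)) NULL else
    m[c("T2", "wilks_lambda", "F", "df1", "df2", "p", "n", "p_dims")]
  json <- list(
    manova_4 = manova_block(res$manova_4),
    manova_6 = manova_block(res$manova_6),
    means = res$means,
    logratio_4 = res$logratio_4,
    posthoc_4 = res$posthoc_4,
    posthoc_leisure = res$posthoc_leisure,
    posthoc_lecture = res$posthoc_lecture)
  jsonlite::write_json(json, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  posthoc <- rbind(
    cbind(family = "4part", res$posthoc_4),
    if (!is.null(res$posthoc_leisure))
      cbind(family = "leisure", res$posthoc_leisure),
    if (!is.null(res$posthoc_lecture))
      cbind(family = "lecture", res$posthoc_lecture))
  utils::write.csv(posthoc, file.path(out_dir, "posthoc.csv"),
                   row.names = FALSE)
  bar4 <- make_barplot_data(res$means$onsite$p4, res$means$online$p4)
  utils::write.csv(bar4, file.path(out_dir, "barplot_data_4part.csv"),
                   row.names = FALSE)
  plots <- list(plot_logratio_bars(bar4, "Whole day (4-part)"))
  if (!is.null(res$means$onsite$p6)) {
    bar6 <- make_barplot_data(res$means$onsite$p6, res$means$online$p6)
    utils::write.csv(bar6, file.path(out_dir, "barplot_data_6part.csv"),
                     row.names = FALSE)
    plots <- c(plots, list(plot_logratio_bars(bar6, "Domain-specific (6-part)")))
  }
  grDevices::pdf(file.path(out_dir, "logratio_barplot.pdf"),
                 width = 6, height = 4)
  for (p in plots) print(p)
  grDevices::dev.off()
  invisible(out_dir)
}
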