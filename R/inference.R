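#' Paired ilr differences between two conditions
#'
#' For each participant present under both conditions, computes
#' `ilr(online) - ilr(onsite)` in pivot coordinates with the given
#' leading part. Because the ilr of a compositional mean equals the mean
#' of the ilr vectors, the column means of this matrix equal the ilr
#' difference of the two compositional means (used as a cross-check).
#'
#' @param pairs data.frame with `participant_id`, `condition` and one
#'   column per part; or a list with matrices `onsite`, `online` (rows
#'   aligned by participant).
#' @param parts character vector naming the composition's parts.
#' @param leading leading part for the pivot basis (default first part).
#' @return n x (D-1) matrix of differences; attribute `"n"`.
#' @export
paired_ilr_differences <- function(pairs, parts, leading = parts[1]) {
  mats <- as_condition_pair(pairs, parts)
  z_on <- pivot_ilr(mats$onsite, leading = leading)
  z_ol <- pivot_ilr(mats$online, leading = leading)
  d <- z_ol - z_on
  attr(d, "n") <- nrow(d)
  attr(d, "leading") <- leading
  d
}

# normalize pairing input to aligned onsite/online matrices (complete cases)
as_condition_pair <- function(pairs, parts) {
  if (is.list(pairs) && !is.data.frame(pairs) &&
      all(c("onsite", "online") %in% names(pairs)))
    return(list(onsite = as.matrix(pairs$onsite[, parts, drop = FALSE]),
                online = as.matrix(pairs$online[, parts, drop = FALSE])))
  stopifnot(is.data.frame(pairs),
            all(c("participant_id", "condition") %in% names(pairs)),
            all(parts %in% names(pairs)))
  on <- pairs[pairs$condition == "onsite", , drop = FALSE]
  ol <- pairs[pairs$condition == "online", , drop = FALSE]
  common <- intersect(on$participant_id, ol$participant_id)
  dropped <- setdiff(unique(pairs$participant_id), common)
  if (length(dropped))
    message("dropping unpaired participant(s): ",
            paste(dropped, collapse = ", "))
  on <- on[match(common, on$participant_id), parts, drop = FALSE]
  ol <- ol[match(common, ol$participant_id), parts, drop = FALSE]
  keep <- stats::complete.cases(on) & stats::complete.cases(ol)
  list(onsite = as.matrix(on[keep, , drop = FALSE]),
       online = as.matrix(ol[keep, , drop = FALSE]))
}

#' Repeated-measures MANOVA for two within-subject conditions
#'
#' A two-level within-subject MANOVA on ilr coordinates is exactly a
#' one-sample Hotelling T-squared test on the paired difference vectors:
#' `T2 = n * dbar' S^-1 dbar`, Wilks `Lambda = (1 + T2/(n-1))^-1`, and
#' `F = ((n - p)/(p (n-1))) T2` on `(p, n - p)` degrees of freedom, with
#' `p` the coordinate dimension.
#'
#' @param diff_matrix n x p matrix of paired ilr differences.
#' @return list of class `manova_result`: `T2`, `wilks_lambda`, `F`,
#'   `df1`, `df2`, `p`, `n`, `p_dims`.
#' @export
rm_manova <- function(diff_matrix) {
  d <- as.matrix(diff_matrix)
  n <- nrow(d); p <- ncol(d)
  if (n <= p) stop("rm_manova: need more participants (n = ", n,
                   ") than coordinates (p = ", p, ")")
  m <- colMeans(d)
  S <- stats::cov(d)
  qr_S <- qr(S)
  if (qr_S$rank < p)
    stop("rm_manova: singular covariance of differences; ",
         "amalgamate parts or provide more data")
  T2 <- as.numeric(n * crossprod(m, solve(S, m)))
  lambda <- 1 / (1 + T2 / (n - 1))
  Fstat <- (n - p) / (p * (n - 1)) * T2
  structure(list(T2 = T2, wilks_lambda = lambda, F = Fstat,
                 df1 = p, df2 = n - p,
                 p = stats::pf(Fstat, p, n - p, lower.tail = FALSE),
                 n = n, p_dims = p),
            class = "manova_result")
}

#' Convert a Wilks Lambda to its exact F statistic
#'
#' For the one-sample (two within-subject level) case,
#' `F = ((n - p)/p) (1 - Lambda)/Lambda` on `(p, n - p)` df.
#'
#' @param lambda Wilks Lambda in (0, 1].
#' @param n number of participants; @param p_dims coordinate dimension.
#' @return the F statistic.
#' @export
wilks_to_f <- function(lambda, n, p_dims) {
  (n - p_dims) / p_dims * (1 - lambda) / lambda
}

#' Post hoc paired t-test on a first pivot coordinate
#'
#' Represents the named behaviour by the first pivot coordinate of the
#' composition with that part leading (its log-ratio to the geometric
#' mean of the remaining parts) and runs a two-sided paired t-test of
#' online vs onsite: mean difference MD with Student-t 95% CI, and
#' Cohen's d = MD / SD(differences) (0.2 / 0.5 / 0.8 read as small /
#' medium / large).
#'
#' @param pairs as in [paired_ilr_differences()].
#' @param parts the composition's part names.
#' @param part the behaviour to lead with.
#' @param conf_level CI level (default 0.95).
#' @return one-row data.frame: `part`, `mean_onsite`, `mean_online`, `t`,
#'   `md`, `ci_lo`, `ci_hi`, `p`, `d`, `n`.
#' @export
pivot_posthoc <- function(pairs, parts, part, conf_level = 0.95) {
  mats <- as_condition_pair(pairs, parts)
  z_on <- pivot_ilr(mats$onsite, leading = part)[, 1]
  z_ol <- pivot_ilr(mats$online, leading = part)[, 1]
  dz <- z_ol - z_on
  n <- length(dz)
  if (n < 2) stop("pivot_posthoc: need at least 2 paired participants")
  md <- mean(dz)
  sdd <- stats::sd(dz)
  if (sdd == 0) {
    if (md == 0) {
      tt <- 0; pv <- 1; ci <- c(0, 0); dd <- 0
    } else {
      warning("zero variance of paired differences with nonzero mean; ",
              "t reported as infinite")
      tt <- sign(md) * Inf; pv <- 0; ci <- c(md, md); dd <- sign(md) * Inf
    }
  } else {
    se <- sdd / sqrt(n)
    tt <- md / se
    pv <- 2 * stats::pt(abs(tt), n - 1, lower.tail = FALSE)
    q <- stats::qt(1 - (1 - conf_level) / 2, n - 1)
    ci <- md + c(-1, 1) * q * se
    dd <- md / sdd
  }
  data.frame(part = part, mean_onsite = mean(z_on), mean_online = mean(z_ol),
             t = tt, md = md, ci_lo = ci[1], ci_hi = ci[2], p = pv, d = dd,
             n = n, stringsAsFactors = FALSE)
}

#' Full paired-condition analysis of a participant-condition table
#'
#' Reproduces the whole inferential surface for a cohort: the 4-part
#' whole-day RM MANOVA with pivot post hoc tests for SL, SB, LPA and
#' MVPA; the 6-part domain-specific RM MANOVA; post hoc tests on the
#' leisure 3-part and lecture 2-part sub-compositions; compositional
#' means per condition; and log-ratio percent changes between condition
#' means. Alpha 0.05; p-values are reported unadjusted by default, with
#' an optional Holm correction across the post hoc family.
#'
#' @param pc_table participant-condition table from
#'   [include_participants()] (`$table`).
#' @param holm apply Holm adjustment to post hoc p-values (default FALSE).
#' @return list of class `coda_analysis`: `manova_4`, `posthoc_4`,
#'   `manova_6`, `posthoc_leisure`, `posthoc_lecture`, `means`,
#'   `logratio_4`.
#' @export
run_full_analysis <- function(pc_table, holm = FALSE) {
  stopifnot(is.data.frame(pc_table), nrow(pc_table) > 0)
  d4 <- paired_ilr_differences(pc_table, parts_4, leading = "SL")
  manova_4 <- rm_manova(d4)
  posthoc_4 <- do.call(rbind, lapply(parts_4, function(p)
    pivot_posthoc(pc_table, parts_4, p)))

  have6 <- all(parts_6 %in% names(pc_table)) &&
    !anyNA(pc_table[, parts_6])
  manova_6 <- posthoc_leisure <- posthoc_lecture <- NULL
  if (have6) {
    d6 <- paired_ilr_differences(pc_table, parts_6, leading = "SL6")
    manova_6 <- rm_manova(d6)
    posthoc_leisure <- do.call(rbind, lapply(parts_leisure, function(p)
      pivot_posthoc(pc_table, parts_leisure, p)))
    posthoc_lecture <- do.call(rbind, lapply(parts_lecture, function(p)
      pivot_posthoc(pc_table, parts_lecture, p)))
  }
  if (holm) {
    fam <- rbind(posthoc_4[, c("part", "p")],
                 if (have6) posthoc_leisure[, c("part", "p")],
                 if (have6) posthoc_lecture[, c("part", "p")])
    adj <- stats::p.adjust(fam$p, method = "holm")
    k <- nrow(posthoc_4)
    posthoc_4$p_holm <- adj[seq_len(k)]
    if (have6) {
      posthoc_leisure$p_holm <- adj[k + seq_len(nrow(posthoc_leisure))]
      posthoc_lecture$p_holm <-
        adj[k + nrow(posthoc_leisure) + seq_len(nrow(posthoc_lecture))]
    }
  }
  means <- lapply(c(onsite = "onsite", online = "online"), function(cond) {
    sub <- pc_table[pc_table$condition == cond, , drop = FALSE]
    out <- list(p4 = compositional_mean(sub[, parts_4], 1440))
    if (have6) {
      out$p6 <- compositional_mean(sub[, parts_6], 1440)
      out$leisure <- compositional_mean(closure(sub[, parts_leisure], 1), 1)
      out$lecture <- compositional_mean(closure(sub[, parts_lecture], 1), 1)
    }
    out
  })
  structure(list(manova_4 = manova_4, posthoc_4 = posthoc_4,
                 manova_6 = manova_6, posthoc_leisure = posthoc_leisure,
                 posthoc_lecture = posthoc_lecture, means = means,
                 logratio_4 = logratio_change(means$onsite$p4,
                                              means$online$p4)),
            class = "coda_analysis")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf(
    "RM MANOVA (one-sample Hotelling T2 on ilr differences)\n  n = %d, p = %d\n  T2 = %.3f, Wilks Lambda = %.3f, F(%d, %d) = %.3f, p = %.3g\n",
    x$n, x$p_dims, x$T2, x$wilks_lambda, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' @export
print.coda_analysis <- function(x, ...) {
  cat("== 4-part 24-h composition (SL, SB, LPA, MVPA) ==\n")
  print(x$manova_4)
  cat("\nPost hoc (first pivot coordinates):\n")
  print(x$posthoc_4, digits = 4, row.names = FALSE)
  if (!is.null(x$manova_6)) {
    cat("\n== 6-part domain-specific composition ==\n")
    print(x$manova_6)
    cat("\nLeisure sub-composition post hoc:\n")
    print(x$posthoc_leisure, digits = 4, row.names = FALSE)
    cat("\nLecture sub-composition post hoc:\n")
    print(x$posthoc_lecture, digits = 4, row.names = FALSE)
  }
  cat("\nLog-ratio change, online vs onsite (4-part):\n")
  print(x$logratio_4, digits = 4, row.names = FALSE)
  invisible(x)
}
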