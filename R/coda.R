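#' Compositional geometry for 24-hour time-use data
#'
#' A daily time-use composition is a vector of non-negative parts (minutes
#' spent asleep, sedentary, in light and in moderate-to-vigorous activity)
#' carrying only relative information and constrained to a constant total
#' (1440 min/day, or 1 when expressed as proportions). These helpers
#' implement the Aitchison-geometry operations the analysis rests on:
#' closure, compositional means, isometric log-ratio (ilr) pivot
#' coordinates and their rotations, amalgamation, and log-ratio change
#' summaries between compositional means.
#'
#' @name coda
NULL

#' Close a vector (or matrix rows) of parts to a fixed total
#'
#' Rescales non-negative parts so they sum to `total`. Zero parts are
#' preserved as zeros; a composition containing zeros must be amalgamated
#' (see [amalgamate()]) or have its zeros replaced (see [replace_zeros()])
#' before any log-ratio operation.
#'
#' @param x numeric vector of parts, or a matrix/data.frame with one
#'   composition per row.
#' @param total the closure constant (default 1).
#' @return object of the same shape as `x`, rows summing to `total`.
#' @export
closure <- function(x, total = 1) {
  stopifnot(is.numeric(total), length(total) == 1L, total > 0)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (any(x < 0)) stop("closure: negative parts are not allowed")
    s <- rowSums(x)
    if (any(s <= 0)) stop("closure: all-zero composition in row(s) ",
                          paste(which(s <= 0), collapse = ", "))
    return(x * (total / s))
  }
  if (any(x < 0)) stop("closure: negative parts are not allowed")
  s <- sum(x)
  if (s <= 0) stop("closure: all parts are zero")
  x * (total / s)
}

#' Compositional (closed geometric) mean
#'
#' The centre of a set of compositions in Aitchison geometry: the closed
#' part-wise geometric mean, `closure(exp(colMeans(log(X))))`. Its ilr
#' image equals the arithmetic mean of the individual ilr vectors, which
#' is why mean pivot coordinates can be read off compositional means.
#'
#' @param x matrix or data.frame, one strictly positive composition per row.
#' @param total closure constant of the result.
#' @return named numeric vector, the compositional mean closed to `total`.
#' @export
compositional_mean <- function(x, total = 1) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (any(x <= 0))
    stop("compositional_mean: zero or negative part found; ",
         "amalgamate or replace zeros before taking a compositional mean")
  closure(exp(colMeans(log(x))), total = total)
}

pivot_order <- function(parts, leading) {
  if (!leading %in% parts)
    stop("leading part '", leading, "' not among parts: ",
         paste(parts, collapse = ", "))
  c(leading, setdiff(parts, leading))
}

#' Isometric log-ratio pivot coordinates
#'
#' Maps a strictly positive D-part composition to D-1 real coordinates.
#' With parts reordered so `leading` comes first, coordinate k is
#' \deqn{z_k = \sqrt{\frac{D-k}{D-k+1}} \,
#'       \ln\frac{x_k}{\left(\prod_{j=k+1}^{D} x_j\right)^{1/(D-k)}}}
#' so the first coordinate contrasts the leading part against the
#' geometric mean of all the others; re-leading each part in turn
#' ("pivot rotation") yields the first coordinate for every behaviour.
#' The map is an isometry: Euclidean distance between coordinate vectors
#' equals Aitchison distance between compositions, and it is invariant to
#' the closure constant.
#'
#' @param x named strictly positive numeric vector, or a matrix/data.frame
#'   of compositions (one per row) with named columns.
#' @param leading name of the part to place first (default: first part).
#' @return numeric vector of length D-1 (or a matrix with D-1 columns),
#'   with attribute `"leading"`; columns named `ilr1`, `ilr2`, ...
#' @export
pivot_ilr <- function(x, leading = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    parts <- colnames(x)
    if (is.null(parts)) stop("pivot_ilr: compositions must have part names")
    if (is.null(leading)) leading <- parts[1]
    ord <- pivot_order(parts, leading)
    z <- t(apply(x, 1L, function(r) pivot_ilr_vec(r[ord])))
    if (ncol(x) == 2L) z <- matrix(z, ncol = 1L)  # apply() drops to vector
    colnames(z) <- paste0("ilr", seq_len(ncol(x) - 1L))
    attr(z, "leading") <- leading
    return(z)
  }
  parts <- names(x)
  if (is.null(parts)) stop("pivot_ilr: composition must have part names")
  if (is.null(leading)) leading <- parts[1]
  z <- pivot_ilr_vec(x[pivot_order(parts, leading)])
  names(z) <- paste0("ilr", seq_along(z))
  attr(z, "leading") <- leading
  z
}

pivot_ilr_vec <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("pivot_ilr: all parts must be finite and strictly positive")
  D <- length(x)
  lx <- log(x)
  vapply(seq_len(D - 1L), function(k) {
    sqrt((D - k) / (D - k + 1)) * (lx[k] - mean(lx[(k + 1L):D]))
  }, numeric(1))
}

#' Inverse of the pivot ilr transform
#'
#' Reconstructs the unique strictly positive composition with the given
#' closure total from pivot coordinates, with `part_names[1]` as the
#' leading part. `pivot_ilr(inverse_pivot_ilr(z, p)) == z`.
#'
#' @param z numeric vector of D-1 finite coordinates.
#' @param part_names character vector of D part names, leading part first.
#' @param total closure constant (default 1).
#' @return named composition closed to `total`.
#' @export
inverse_pivot_ilr <- function(z, part_names, total = 1) {
  D <- length(part_names)
  stopifnot(length(z) == D - 1L, all(is.finite(z)))
  # invert the sequential contrast: accumulate log-parts back to front
  lx <- numeric(D)
  for (k in rev(seq_len(D - 1L))) {
    m <- mean(lx[(k + 1L):D])
    lx[k] <- z[k] / sqrt((D - k) / (D - k + 1)) + m
  }
  out <- closure(stats::setNames(exp(lx), part_names), total = total)
  out
}

#' Amalgamate (sum) parts of a composition
#'
#' Sums named groups of parts into coarser parts, preserving the total.
#' This is the sanctioned treatment of structural (true) zeros: for
#' example lecture-time LPA and MVPA are merged into a single PA part
#' because many students accumulate genuinely zero lecture MVPA.
#'
#' @param x named numeric vector, or matrix/data.frame of compositions.
#' @param merge_map named list; each element is a character vector of part
#'   names to sum, the element's name is the new part. Parts not mentioned
#'   are kept as-is, in their original order relative to the merged parts
#'   (a merged part takes the position of its first member).
#' @return composition(s) with merged parts.
#' @export
amalgamate <- function(x, merge_map) {
  if (is.data.frame(x)) x <- as.matrix(x)
  mat <- if (is.matrix(x)) x else matrix(x, nrow = 1,
                                         dimnames = list(NULL, names(x)))
  parts <- colnames(mat)
  members <- unlist(merge_map, use.names = FALSE)
  if (anyDuplicated(members))
    stop("amalgamate: merge groups overlap on part(s) ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  if (!all(members %in% parts))
    stop("amalgamate: unknown part(s) ",
         paste(setdiff(members, parts), collapse = ", "))
  new_cols <- list()
  consumed <- character(0)
  for (p in parts) {
    if (p %in% consumed) next
    grp <- which(vapply(merge_map, function(g) p %in% g, logical(1)))
    if (length(grp)) {
      g <- merge_map[[grp[1]]]
      new_cols[[names(merge_map)[grp[1]]]] <-
        rowSums(mat[, g, drop = FALSE])
      consumed <- c(consumed, g)
    } else {
      new_cols[[p]] <- mat[, p]
    }
  }
  out <- do.call(cbind, new_cols)
  if (!is.matrix(x)) return(out[1, ])
  out
}

#' Multiplicative replacement of zero parts
#'
#' Optional escape hatch for rounded zeros: replaces zeros by
#' `delta = 0.5 * min(positive observed values)` (or a supplied `delta`)
#' and rescales the positive parts multiplicatively so row totals are
#' preserved. Emits a warning; amalgamation is the preferred route for
#' structural zeros.
#'
#' @param x matrix/data.frame of compositions (or a single vector).
#' @param delta replacement value; default half the smallest positive entry.
#' @return object of the same shape with strictly positive entries.
#' @export
replace_zeros <- function(x, delta = NULL) {
  vec <- !is.matrix(x) && !is.data.frame(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  mat <- if (vec) matrix(x, nrow = 1, dimnames = list(NULL, names(x))) else x
  if (!any(mat == 0)) return(x)
  if (is.null(delta)) delta <- 0.5 * min(mat[mat > 0])
  warning("replace_zeros: replacing ", sum(mat == 0),
          " zero part(s) by delta = ", signif(delta, 4),
          "; consider amalgamation for structural zeros")
  out <- t(apply(mat, 1L, function(r) {
    z <- r == 0
    if (!any(z)) return(r)
    tot <- sum(r)
    r[z] <- delta
    r[!z] <- r[!z] * (tot - delta * sum(z)) / tot
    r
  }))
  colnames(out) <- colnames(mat)
  if (vec) out[1, ] else out
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between the ilr images; independent of the leading
#' part and of the closure constant.
#'
#' @param x,y strictly positive named compositions with the same parts.
#' @return non-negative scalar.
#' @export
aitchison_dist <- function(x, y) {
  stopifnot(setequal(names(x), names(y)))
  y <- y[names(x)]
  sqrt(sum((pivot_ilr(x) - pivot_ilr(y))^2))
}

#' Log-ratio change between two compositional means
#'
#' For each part, the log of the ratio of its share under condition `b`
#' to its share under condition `a`, and the corresponding percent change
#' `exp(log-ratio) * 100 - 100`. This is the quantity displayed in
#' geometric-mean bar plots comparing two conditions.
#'
#' @param mean_a,mean_b named compositions with identical parts (any
#'   closure; shares are formed internally).
#' @return data.frame with columns `part`, `log_ratio`, `pct_change`.
#' @export
logratio_change <- function(mean_a, mean_b) {
  if (!setequal(names(mean_a), names(mean_b)) ||
      is.null(names(mean_a)))
    stop("logratio_change: compositions must share the same named parts")
  mean_b <- mean_b[names(mean_a)]
  a <- closure(mean_a, 1)
  b <- closure(mean_b, 1)
  lr <- log(b / a)
  data.frame(part = names(mean_a),
             log_ratio = unname(lr),
             pct_change = unname(exp(lr) * 100 - 100),
             stringsAsFactors = FALSE)
}

#' Canonical behaviour orders
#'
#' Part orders used throughout: the 4-part whole-day composition
#' SL, SB, LPA, MVPA; the 6-part domain-specific composition; and the
#' leisure / lecture sub-compositions.
#' @name part_orders
#' @export
parts_4 <- c("SL", "SB", "LPA", "MVPA")

#' @rdname part_orders
#' @export
parts_6 <- c("SL6", "SB_leisure", "LPA_leisure", "MVPA_leisure",
             "SB_lecture", "PA_lecture")

#' @rdname part_orders
#' @export
parts_leisure <- c("SB_leisure", "LPA_leisure", "MVPA_leisure")

#' @rdname part_orders
#' @export
parts_lecture <- c("SB_lecture", "PA_lecture")
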