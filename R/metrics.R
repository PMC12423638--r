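# Mask-agreement metrics, the DSC quality rubric, cohort summaries and paired
# Wilcoxon comparisons between pipelines.

#' Compare two binary masks
#'
#' Views the overlap as a confusion matrix: voxels in both masks are true
#' positives, voxels only in the manual mask are false negatives, voxels only
#' in the automated mask are false positives, the rest true negatives. From
#' these: `dsc = 2 tp / (2 tp + fp + fn)`, `miss_rate = fn / (tp + fn)`,
#' `fdr = fp / (tp + fp)`, and `overlap`, by default the Jaccard index
#' `tp / (tp + fp + fn) = dsc / (2 - dsc)` (set `overlap_def = "sensitivity"`
#' for the alternative reading `tp / (tp + fn)`).
#'
#' Degenerate cases: both masks empty gives dsc 1 and zero rates (vacuous
#' perfect agreement, with a warning); exactly one empty gives dsc 0, with
#' the undefined rate set to its harmless extreme.
#'
#' @param manual,auto [binary_mask()]s (or logical arrays) on the same grid.
#' @param overlap_def `"jaccard"` (default) or `"sensitivity"`.
#' @return An object of class `mask_comparison`: a one-row data.frame with
#'   columns `tp, fp, fn, tn, dsc, overlap, miss_rate, fdr`.
#' @export
compare_masks <- function(manual, auto, overlap_def = c("jaccard", "sensitivity")) {
  overlap_def <- match.arg(overlap_def)
  m <- if (inherits(manual, "vol3d")) manual$data else as.array(manual)
  a <- if (inherits(auto, "vol3d")) auto$data else as.array(auto)
  if (inherits(manual, "vol3d") && inherits(auto, "vol3d"))
    stopifnot_same_grid(manual, auto, "masks")
  else if (!identical(dim(m), dim(a))) stop("masks are not on the same grid")
  m <- as.logical(m); a <- as.logical(a)
  tp <- sum(m & a); fp <- sum(!m & a); fn <- sum(m & !a)
  tn <- length(m) - tp - fp - fn
  if (tp + fp + fn == 0L) {
    warning("both masks are empty; reporting vacuous perfect agreement")
    out <- data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
                      dsc = 1, overlap = 1, miss_rate = 0, fdr = 0)
  } else {
    dsc <- 2 * tp / (2 * tp + fp + fn)
    overlap <- if (overlap_def == "jaccard") tp / (tp + fp + fn)
               else if (tp + fn > 0) tp / (tp + fn) else 0
    miss_rate <- if (tp + fn > 0) fn / (tp + fn) else 0
    fdr <- if (tp + fp > 0) fp / (tp + fp) else 0
    out <- data.frame(tp = tp, fp = fp, fn = fn, tn = tn, dsc = dsc,
                      overlap = overlap, miss_rate = miss_rate, fdr = fdr)
  }
  class(out) <- c("mask_comparison", "data.frame")
  out
}

#' Classify a Dice coefficient into the standard quality rubric
#'
#' Half-open bins with boundaries assigned upward: poor `[0, 0.6)`, good
#' `[0.6, 0.7)`, high `[0.7, 0.8)`, excellent `[0.8, 1]`.
#'
#' @param dsc Numeric vector of Dice coefficients in `[0, 1]`.
#' @return Factor with levels poor < good < high < excellent.
#' @export
classify_dsc <- function(dsc) {
  if (any(!is.finite(dsc)) || any(dsc < 0) || any(dsc > 1))
    stop("dsc values must lie in [0, 1]")
  cut(dsc, breaks = c(-Inf, 0.6, 0.7, 0.8, Inf), right = FALSE,
      labels = c("poor", "good", "high", "excellent"), ordered_result = TRUE)
}

#' Summarise a cohort of mask comparisons
#'
#' Medians and interquartile ranges per metric and pipeline (quartiles by
#' linear interpolation between order statistics, i.e. [stats::quantile()]
#' type 7, fixed for reproducibility), DSC rubric category counts, and counts
#' at the reporting thresholds (DSC >= 0.7, DSC < 0.6).
#'
#' @param cases A list of [compare_masks()] results (or a data.frame with the
#'   metric columns).
#' @param pipeline_labels Optional character vector, one label per case.
#' @return An object of class `cohort_summary`: list with `per_case` (the
#'   assembled table), `stats` (median/IQR per metric per pipeline) and
#'   `categories` (rubric counts per pipeline).
#' @export
summarize_cohort <- function(cases, pipeline_labels = NULL) {
  if (is.data.frame(cases)) tab <- cases
  else {
    if (!length(cases)) stop("no cases supplied")
    tab <- do.call(rbind, lapply(cases, as.data.frame))
  }
  if (!nrow(tab)) stop("no cases supplied")
  if (is.null(pipeline_labels)) pipeline_labels <- rep("pipeline", nrow(tab))
  if (length(pipeline_labels) != nrow(tab))
    stop("pipeline_labels must have one entry per case")
  tab$pipeline <- pipeline_labels
  metrics <- intersect(c("dsc", "overlap", "miss_rate", "fdr"), names(tab))
  stats <- do.call(rbind, lapply(split(tab, tab$pipeline), function(g) {
    do.call(rbind, lapply(metrics, function(m) {
      q <- quantile(g[[m]], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      data.frame(pipeline = g$pipeline[1], metric = m, median = q[2],
                 iqr = q[3] - q[1], q1 = q[1], q3 = q[3], n = nrow(g))
    }))
  }))
  rownames(stats) <- NULL
  categories <- do.call(rbind, lapply(split(tab, tab$pipeline), function(g) {
    cat_counts <- table(classify_dsc(g$dsc))
    data.frame(pipeline = g$pipeline[1],
               poor = as.integer(cat_counts[["poor"]]),
               good = as.integer(cat_counts[["good"]]),
               high = as.integer(cat_counts[["high"]]),
               excellent = as.integer(cat_counts[["excellent"]]),
               dsc_ge_0.7 = sum(g$dsc >= 0.7),
               dsc_lt_0.6 = sum(g$dsc < 0.6))
  }))
  rownames(categories) <- NULL
  structure(list(per_case = tab, stats = stats, categories = categories),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$stats, row.names = FALSE)
  cat("\nDSC categories:\n")
  print(x$categories, row.names = FALSE)
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank statistic with zero-difference exclusion and mid-rank ties.
#' For n (nonzero differences) up to 25 the p-value is exact, from the full
#' randomisation distribution of sign assignments (computed by a
#' generating-function convolution over the doubled ranks, equivalent to
#' enumerating all 2^n sign patterns); above 25 a normal approximation with
#' tie correction and continuity correction is used. One-tailed per
#' `alternative`: `"greater"` tests whether `x` exceeds `y`.
#'
#' @param x,y Paired metric vectors of equal length (>= 5).
#' @param alternative `"greater"` or `"less"`.
#' @return The p-value, with attributes `statistic` (W+, the positive-rank
#'   sum), `n_used` (pairs after zero exclusion) and `exact`.
#' @export
wilcoxon_paired <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 5L) stop("need at least 5 pairs")
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) {
    warning("all differences are zero; p = 1")
    out <- 1
    attr(out, "statistic") <- 0
    attr(out, "n_used") <- 0L
    attr(out, "exact") <- TRUE
    return(out)
  }
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    # exact randomisation distribution over doubled (integer) ranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dp <- numeric(total + 1L)
    dp[1L] <- 1
    for (rv in r2) {
      shifted <- c(numeric(rv), dp[seq_len(total + 1L - rv)])
      dp <- dp + shifted
    }
    probs <- dp / 2^n
    w2 <- as.integer(round(2 * W))
    p <- if (alternative == "greater") sum(probs[(w2 + 1L):(total + 1L)])
         else sum(probs[1L:(w2 + 1L)])
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sig <- sqrt(sig2)
    p <- if (alternative == "greater") pnorm((W - mu - 0.5) / sig, lower.tail = FALSE)
         else pnorm((W - mu + 0.5) / sig)
    exact <- FALSE
  }
  p <- min(max(p, 0), 1)
  out <- p
  attr(out, "statistic") <- W
  attr(out, "n_used") <- n
  attr(out, "exact") <- exact
  out
}

#' Pairwise pipeline comparison table
#'
#' Runs [wilcoxon_paired()] for every ordered pipeline pair and metric with
#' the conventional directions: `"greater"` for DSC and overlap (higher is
#' better), `"less"` for miss rate and FDR (lower is better).
#'
#' @param metric_table data.frame with a `pipeline` column and metric columns
#'   (`dsc`, `overlap`, `miss_rate`, `fdr`), cases aligned across pipelines
#'   in row order within each pipeline.
#' @return data.frame of pipeline pairs x metrics with statistics/p-values.
#' @export
compare_pipelines <- function(metric_table) {
  pls <- unique(metric_table$pipeline)
  if (length(pls) < 2L) stop("need at least two pipelines")
  metrics <- intersect(c("dsc", "overlap", "miss_rate", "fdr"),
                       names(metric_table))
  alt_for <- c(dsc = "greater", overlap = "greater",
               miss_rate = "less", fdr = "less")
  rows <- list()
  for (a in pls) for (b in setdiff(pls, a)) {
    xa <- metric_table[metric_table$pipeline == a, , drop = FALSE]
    xb <- metric_table[metric_table$pipeline == b, , drop = FALSE]
    if (nrow(xa) != nrow(xb)) stop("pipelines have unequal case counts")
    for (m in metrics) {
      p <- wilcoxon_paired(xa[[m]], xb[[m]], alt_for[[m]])
      rows[[length(rows) + 1L]] <- data.frame(
        pipeline_a = a, pipeline_b = b, metric = m,
        alternative = alt_for[[m]], statistic = attr(p, "statistic"),
        n = attr(p, "n_used"), p_value = as.numeric(p))
    }
  }
  do.call(rbind, rows)
}
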