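#' Summarize the final outcomes of repeated runs
#'
#' Best/Worst/Mean/Std over the `H` final outcomes of independent runs of
#' one algorithm on one dataset. Orientation follows error rates and subset
#' sizes: lower is better, so `best = min` and `worst = max`. The standard
#' deviation uses the `H - 1` denominator.
#'
#' @param values numeric vector of `H >= 2` final outcomes.
#' @return list of class `run_summary`: `best`, `worst`, `mean`, `std`,
#'   `H`, `values`.
#' @examples
#' summarize_runs(c(0.1, 0.2, 0.3))
#' @export
summarize_runs <- function(values) {
  if (length(values) < 2L) stop("need at least 2 run outcomes", call. = FALSE)
  structure(
    list(best = min(values), worst = max(values),
         mean = mean(values), std = stats::sd(values),
         H = length(values), values = values),
    class = "run_summary"
  )
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary H=%d> best %.4g | mean %.4g | worst %.4g | std %.4g\n",
              x$H, x$best, x$mean, x$worst, x$std))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Nonparametric two-sample comparison of final error rates (or subset
#' sizes) between two algorithms on one dataset. Uses the exact rank-sum
#' distribution when both samples are small and tie-free, otherwise the
#' normal approximation with tie correction. A p-value below 0.05 is
#' conventionally read as a significant difference.
#'
#' @param sample_a,sample_b numeric vectors of outcomes (nonempty).
#' @return the two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # 0.1
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  # identical samples: no rank separation, maximal p
  suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, alternative = "two.sided")$p.value
  )
}

#' Friedman mean ranks across datasets
#'
#' Within each dataset (row), algorithms (columns) are ranked ascending —
#' rank 1 for the lowest error — with ties receiving average ranks, so each
#' row's ranks sum to `k (k + 1) / 2`. The primary output is the
#' per-algorithm mean rank over datasets (lower is better); the Friedman
#' chi-square statistic and p-value are attached for reference.
#'
#' @param results numeric matrix, datasets in rows, algorithms in columns
#'   (at least 2 columns).
#' @return list of class `friedman_ranks`: `mean_ranks` (named by
#'   algorithm when column names exist), `ranks` (the full rank matrix),
#'   `statistic` and `p_value` (from the Friedman chi-square test when
#'   there are at least 2 rows, else `NA`).
#' @export
friedman_mean_ranks <- function(results) {
  results <- as.matrix(results)
  if (ncol(results) < 2L) stop("need at least 2 algorithms", call. = FALSE)
  if (nrow(results) < 1L) stop("need at least 1 dataset row", call. = FALSE)
  ranks <- t(apply(results, 1L, rank))
  mean_ranks <- colMeans(ranks)
  stat <- p <- NA_real_
  if (nrow(results) >= 2L) {
    ft <- stats::friedman.test(results)
    stat <- unname(ft$statistic)
    p <- ft$p.value
  }
  structure(
    list(mean_ranks = mean_ranks, ranks = ranks, statistic = stat,
         p_value = p),
    class = "friedman_ranks"
  )
}

#' @export
print.friedman_ranks <- function(x, ...) {
  cat("<friedman_ranks> mean ranks (lower is better):\n")
  print(round(x$mean_ranks, 3))
  if (is.finite(x$statistic)) {
    cat(sprintf("chi-square %.3f, p = %.4g\n", x$statistic, x$p_value))
  }
  invisible(x)
}

#' Average convergence traces across runs
#'
#' Pointwise mean of equal-length best-so-far traces; since each input
#' trace is nonincreasing, so is the mean. Used to draw averaged
#' convergence curves over repeated runs.
#'
#' @param traces list of numeric vectors, all the same length.
#' @return numeric vector, the pointwise mean trace.
#' @export
aggregate_traces <- function(traces) {
  if (length(traces) == 0L) stop("no traces supplied", call. = FALSE)
  lens <- lengths(traces)
  if (length(unique(lens)) != 1L) {
    stop("ragged traces: lengths ", paste(unique(lens), collapse = ", "),
         call. = FALSE)
  }
  colMeans(do.call(rbind, traces))
}
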