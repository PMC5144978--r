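#' Two-class mean difference and pooled standard error
#'
#' The building block of the SAM moderated t statistic: for one gene,
#' `mean_diff = mean(group1) - mean(group2)` and the Tusher-style pooled
#' standard error
#' `s = sqrt((1/n1 + 1/n2) * (SS1 + SS2) / (n1 + n2 - 2))`,
#' where SSg is the within-group sum of squared deviations.
#'
#' @param group1,group2 Numeric vectors with at least 2 values each.
#' @return List with `mean_diff` and `s`.
#' @export
pooled_denominator <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  ss1 <- sum((group1 - mean(group1))^2)
  ss2 <- sum((group2 - mean(group2))^2)
  list(mean_diff = mean(group1) - mean(group2),
       s = sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2)))
}

# Vectorized two-class statistics over all genes of a matrix.
# values: genes x samples; in_group: logical over samples.
two_class_stats <- function(values, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group)
  if (n1 < 2L || n2 < 2L)
    stop("both the cluster and its complement need at least 2 samples")
  x1 <- values[, in_group, drop = FALSE]
  x2 <- values[, !in_group, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  list(mean_diff = m1 - m2,
       s = sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2)))
}

#' Estimate the SAM fudge factor s0
#'
#' `percentile_grid` is the Tusher/Chu procedure: candidate values of s0 are
#' the percentiles `0, 0.05, ..., 1` of the gene-wise standard errors s; for
#' each candidate the genes are split into 100 windows by quantiles of s, the
#' median absolute deviation of the moderated statistic d = mean_diff/(s+s0)
#' is computed per window, and the candidate minimizing the coefficient of
#' variation of these window MADs is chosen.  `fixed_percentile` simply takes
#' the `fixed_q` quantile of s.
#'
#' @param mean_diffs,s_values Gene-wise numerators and pooled standard errors
#'   (equal length; at least 100 genes for `percentile_grid`).
#' @param method `"percentile_grid"` or `"fixed_percentile"`.
#' @param fixed_q Quantile of s used by `fixed_percentile` (default 0.05).
#' @return Nonnegative scalar s0.
#' @export
estimate_s0 <- function(mean_diffs, s_values,
                        method = c("percentile_grid", "fixed_percentile"),
                        fixed_q = 0.05) {
  method <- match.arg(method)
  stopifnot(length(mean_diffs) == length(s_values))
  if (all(s_values == 0)) stop("all pooled standard errors are zero")
  if (method == "fixed_percentile")
    return(unname(stats::quantile(s_values, fixed_q)))
  if (length(s_values) < 100L)
    stop("percentile_grid needs at least 100 genes")
  alphas <- seq(0, 1, by = 0.05)
  candidates <- unname(stats::quantile(s_values, alphas))
  # 100 windows by quantiles of s; constant s collapses to one window,
  # in which case every candidate is equivalent and the smallest is returned.
  breaks <- unique(stats::quantile(s_values, seq(0, 1, by = 0.01)))
  if (length(breaks) < 2L) return(candidates[1L])
  win <- cut(s_values, breaks, include.lowest = TRUE)
  cvs <- vapply(candidates, function(s0) {
    d <- mean_diffs / (s_values + s0)
    mads <- tapply(d, win, stats::mad)
    mads <- mads[!is.na(mads)]
    if (mean(mads) == 0) return(Inf)
    stats::sd(mads) / mean(mads)
  }, numeric(1L))
  candidates[which.min(cvs)]
}

#' SAM moderated t statistics for every cluster of a partition
#'
#' Summarizes each cluster of one dataset as a vector of moderated
#' t statistics over the full shared gene universe: for cluster c and gene i,
#' `d_i = mean_diff_i / (s_i + s0)` comparing the cluster's samples against
#' all other samples of the same dataset (one-vs-rest), with the fudge factor
#' s0 estimated once per contrast.  At k = 2 the two columns are exact
#' negations of each other.
#'
#' @param dataset An `expr_dataset`.
#' @param assignment A `cluster_assignment` on the same samples.
#' @param gene_universe Ordered character vector of genes to score (default:
#'   all genes of the dataset).  Must be shared across studies for the
#'   downstream concordance comparison to be meaningful.
#' @param s0_method Passed to [estimate_s0()].
#' @param s0 Optional fixed numeric s0 overriding estimation (`s0 = 0` gives
#'   the unmoderated pooled-t statistic).
#' @return A `tscore_matrix`: list with `dataset_name`, `algorithm`, `k`,
#'   `scores` (genes x k), and `s0` (per-cluster vector).
#' @export
moderated_t_matrix <- function(dataset, assignment,
                               gene_universe = genes(dataset),
                               s0_method = "percentile_grid", s0 = NULL) {
  stopifnot(is_expr_dataset(dataset),
            inherits(assignment, "cluster_assignment"))
  if (!setequal(names(assignment$labels), samples(dataset)))
    stop("assignment does not cover exactly the dataset's samples")
  ds <- subset_dataset(dataset, genes = gene_universe)
  labels <- assignment$labels[samples(ds)]
  k <- assignment$k
  scores <- matrix(NA_real_, nrow(ds$values), k,
                   dimnames = list(genes(ds), paste0("cluster", seq_len(k))))
  s0_used <- numeric(k)
  for (c in seq_len(k)) {
    st <- two_class_stats(ds$values, labels == c)
    s0_c <- if (!is.null(s0)) s0 else estimate_s0(st$mean_diff, st$s, s0_method)
    s0_used[c] <- s0_c
    # zero numerator dominates: a gene with equal group means scores 0 even
    # when its pooled standard error (plus s0) is 0
    scores[, c] <- ifelse(st$mean_diff == 0, 0,
                          st$mean_diff / (st$s + s0_c))
  }
  if (!all(is.finite(scores)))
    stop("non-finite moderated t scores; use a positive s0 for ",
         "zero-dispersion genes")
  structure(list(dataset_name = dataset$name, algorithm = assignment$algorithm,
                 k = k, scores = scores, s0 = s0_used),
            class = "tscore_matrix")
}

#' @export
print.tscore_matrix <- function(x, ...) {
  cat(sprintf("tscore_matrix: '%s' %s k=%d, %d genes, s0 = %s\n",
              x$dataset_name, x$algorithm, x$k, nrow(x$scores),
              paste(signif(x$s0, 3), collapse = "/")))
  invisible(x)
}
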