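#' Rank genes by variability
#'
#' Scores every gene of a dataset by a dispersion statistic: `mad` is the
#' median absolute deviation about the gene median scaled by the consistency
#' constant 1.4826 (so it estimates the standard deviation under normality),
#' `variance` is the unbiased sample variance.
#'
#' @param dataset An `expr_dataset` with at least two samples.
#' @param statistic `"mad"` or `"variance"`.
#' @return Named numeric vector, one nonnegative score per gene.
#' @export
gene_variability <- function(dataset, statistic = c("mad", "variance")) {
  stopifnot(is_expr_dataset(dataset), ncol(dataset$values) >= 2L)
  statistic <- match.arg(statistic)
  x <- dataset$values
  if (statistic == "mad") {
    med <- apply(x, 1L, stats::median)
    scores <- 1.4826 * apply(abs(x - med), 1L, stats::median)
  } else {
    mu <- rowMeans(x)
    scores <- rowSums((x - mu)^2) / (ncol(x) - 1L)
  }
  names(scores) <- rownames(x)
  scores
}

#' Select the union of each study's most variable genes
#'
#' Within each dataset the `n_per_dataset` top-scoring genes are taken (ties
#' at the cutoff broken by lexicographic gene order, for determinism), and
#' the union across datasets is returned together with per-study provenance.
#' All datasets must share one gene universe; run [intersect_gene_universe()]
#' first.
#'
#' @param datasets List of `expr_dataset` objects on a common gene universe.
#' @param n_per_dataset Number of genes selected per study (default 1500).
#' @param statistic Dispersion statistic passed to [gene_variability()].
#' @return A `gene_set` object: list with `genes` (sorted union) and
#'   `provenance` (study -> its selected genes).
#' @export
select_union_gene_set <- function(datasets, n_per_dataset = 1500L,
                                  statistic = c("mad", "variance")) {
  statistic <- match.arg(statistic)
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  universe <- genes(datasets[[1L]])
  for (d in datasets)
    if (!identical(sort(genes(d)), sort(universe)))
      stop("datasets do not share a gene universe; run intersect_gene_universe()")
  if (n_per_dataset > length(universe))
    stop("n_per_dataset exceeds the gene-universe size")
  provenance <- lapply(datasets, function(d) {
    sc <- gene_variability(d, statistic)
    ord <- order(-sc, names(sc))  # score desc, then lexicographic
    sort(names(sc)[ord[seq_len(n_per_dataset)]])
  })
  names(provenance) <- vapply(datasets, function(d) d$name, character(1L))
  structure(list(genes = sort(unique(unlist(provenance, use.names = FALSE))),
                 provenance = provenance,
                 n_per_dataset = as.integer(n_per_dataset),
                 statistic = statistic),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set: %d genes (union of %d per study, %s) from %d studies\n",
              length(x$genes), x$n_per_dataset, x$statistic,
              length(x$provenance)))
  invisible(x)
}
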