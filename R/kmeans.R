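#' Cluster assignment container
#'
#' @param dataset_name Study identifier.
#' @param algorithm `"kmeans"` or `"nmf"`.
#' @param k Number of clusters.
#' @param labels Named integer vector (names = sample ids, values in 1..k);
#'   every cluster index must be populated.
#' @param seed Seed that produced the assignment.
#' @param objective Within-cluster sum of squares (k-means) or reconstruction
#'   divergence (NMF) of the returned solution.
#' @return A `cluster_assignment` object.
#' @export
cluster_assignment <- function(dataset_name, algorithm, k, labels, seed,
                               objective) {
  k <- as.integer(k)
  labels <- stats::setNames(as.integer(labels), names(labels))
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    stop("labels must be uniquely named by sample id")
  if (!all(labels >= 1L & labels <= k))
    stop("cluster indices must lie in 1..k")
  if (length(unique(labels)) != k)
    stop("every cluster index 1..k must contain at least one sample")
  structure(list(dataset_name = dataset_name, algorithm = algorithm, k = k,
                 labels = labels, seed = seed, objective = objective),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %s on '%s', k=%d (sizes %s), objective %.4g\n",
              x$algorithm, x$dataset_name, x$k,
              paste(tabulate(x$labels, x$k), collapse = "/"), x$objective))
  invisible(x)
}

#' Best-of-N k-means partition of one dataset
#'
#' Samples are clustered as observations in the gene-set-restricted,
#' per-gene-centered space with Euclidean k-means.  The algorithm is run
#' `n_init` times from seeded random starts (initial centers drawn as k
#' distinct samples) and the run with the lowest within-cluster sum of
#' squares is kept.  Runs that leave a cluster empty are discarded and
#' redrawn, up to a retry cap.
#'
#' @param dataset An `expr_dataset`.
#' @param gene_set A `gene_set` object or character vector of genes to
#'   cluster on (must be a subset of the dataset's genes).
#' @param k Number of clusters, `2 <= k <=` number of samples.
#' @param n_init Number of random restarts (default 20).
#' @param seed Integer seed; restart r uses a seed derived from it.
#' @param center Pre-clustering per-gene transform, see [center_genes()].
#' @return A `cluster_assignment` with `algorithm = "kmeans"`.
#' @export
kmeans_partition <- function(dataset, gene_set, k, n_init = 20L, seed = 1L,
                             center = "median_center") {
  stopifnot(is_expr_dataset(dataset))
  gs <- if (inherits(gene_set, "gene_set")) gene_set$genes else gene_set
  gs <- intersect(gs, genes(dataset))
  if (!length(gs)) stop("gene set empty after restriction to dataset genes")
  n <- ncol(dataset$values)
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= number of samples")
  ds <- center_genes(subset_dataset(dataset, genes = gs), center)
  obs <- t(ds$values)  # samples x genes

  if (k == n) {  # exact solution: every sample its own cluster
    return(cluster_assignment(dataset$name, "kmeans", k,
                              stats::setNames(seq_len(n), rownames(obs)),
                              seed, 0))
  }
  best <- NULL
  run <- 0L
  attempts <- 0L
  max_attempts <- n_init * 5L
  while (run < n_init && attempts < max_attempts) {
    attempts <- attempts + 1L
    set.seed(derive_seed(seed, attempts))
    centers <- obs[sample.int(n, k), , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(obs, centers = centers, iter.max = 100L)),
      error = function(e) NULL)
    if (is.null(fit) || any(fit$size == 0L)) next  # empty cluster: redraw
    run <- run + 1L
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    stop("k-means failed to produce a valid partition for '",
         dataset$name, "' at k=", k)
  labels <- stats::setNames(best$cluster, rownames(obs))
  cluster_assignment(dataset$name, "kmeans", k, labels, seed,
                     best$tot.withinss)
}
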