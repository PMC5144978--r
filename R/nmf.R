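#' Nonnegative matrix factorization by multiplicative KL updates
#'
#' Factorizes a nonnegative matrix V (features x samples) as V ~ W H with
#' k metagenes, minimizing the generalized Kullback-Leibler divergence
#' D(V || WH) = sum(V log(V/WH) - V + WH) with the classic multiplicative
#' update rules, from a seeded uniform random initialization.  Iteration
#' stops when the sample connectivity (which metagene each sample maximizes)
#' has been unchanged for `stable_checks` consecutive checks (performed every
#' `check_every` iterations), when the relative divergence change between
#' checks falls below `tol`, or at `max_iter`.
#'
#' @param nonneg_matrix Nonnegative numeric matrix, features x samples.
#' @param k Factorization rank, `2 <= k <= min(dim)` (`k = 1` is permitted
#'   for degenerate testing).
#' @param max_iter Maximum number of update iterations.
#' @param tol Relative divergence-change convergence threshold.
#' @param seed Integer seed for the random initialization.
#' @param check_every,stable_checks Connectivity-based stopping rule.
#' @param track If `TRUE`, record the divergence after every iteration in
#'   the `divergence_trace` element (used to audit monotonicity).
#' @return List with `W` (features x k), `H` (k x samples), `divergence`,
#'   `n_iter`, and optionally `divergence_trace`.
#' @export
nmf_factorize <- function(nonneg_matrix, k, max_iter = 1000L, tol = 1e-6,
                          seed = 1L, check_every = 10L, stable_checks = 4L,
                          track = FALSE) {
  V <- nonneg_matrix
  stopifnot(is.matrix(V), is.numeric(V))
  if (any(V < 0)) stop("NMF input must be nonnegative")
  if (k < 1L || k > min(dim(V)))
    stop("k must lie in 1..min(dim(V))")
  eps <- .Machine$double.eps
  n <- ncol(V)
  m <- nrow(V)

  set.seed(as.integer(seed))
  W <- matrix(stats::runif(m * k), m, k)
  H <- matrix(stats::runif(k * n), k, n)

  kl_div <- function(WH) {
    pos <- V > 0
    sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
  }

  trace <- if (track) numeric(0L) else NULL
  conn_prev <- integer(0L)
  stable <- 0L
  div_prev <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    WH <- W %*% H + eps
    H <- H * (crossprod(W, V / WH)) / pmax(colSums(W), eps)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / rep(pmax(rowSums(H), eps),
                                       each = m)
    if (track) trace <- c(trace, kl_div(W %*% H + eps))
    if (iter %% check_every == 0L || iter == max_iter) {
      assign_now <- apply(H, 2L, which.max)
      if (identical(assign_now, conn_prev)) stable <- stable + 1L
      else { stable <- 0L; conn_prev <- assign_now }
      div_now <- kl_div(W %*% H + eps)
      if (stable >= stable_checks) break
      if (is.finite(div_prev) &&
          abs(div_prev - div_now) <= tol * max(div_prev, eps)) break
      div_prev <- div_now
    }
  }
  out <- list(W = W, H = H, divergence = kl_div(W %*% H + eps), n_iter = iter)
  if (track) out$divergence_trace <- trace
  out
}

#' Assign samples to metagenes
#'
#' Each sample goes to the metagene (row of H) with the largest coefficient;
#' exact ties are broken toward the lowest cluster index and reported in the
#' `ties` attribute.  An all-zero column is unassignable and raises an error.
#'
#' @param H Nonnegative k x samples coefficient matrix.
#' @return Integer vector of cluster indices in 1..k (named if H has
#'   colnames), with attribute `ties` listing tied samples.
#' @export
nmf_assign <- function(H) {
  stopifnot(is.matrix(H))
  if (any(H < 0)) stop("H must be nonnegative")
  zero_col <- colSums(H) == 0
  if (any(zero_col))
    stop("unassignable all-zero H column(s): ",
         paste(which(zero_col), collapse = ", "))
  labels <- apply(H, 2L, which.max)  # which.max takes the first maximum
  tied <- apply(H, 2L, function(col) sum(col == max(col)) > 1L)
  if (!is.null(colnames(H))) names(labels) <- colnames(H)
  attr(labels, "ties") <- which(tied)
  labels
}

#' Single best-of-N NMF clustering of one dataset
#'
#' Restricts to the gene set, centers genes, folds the signed matrix into a
#' nonnegative one, runs `n_init` seeded factorizations and keeps the one
#' with the lowest divergence; samples are assigned by [nmf_assign()].
#'
#' @inheritParams kmeans_partition
#' @param n_init Number of random initializations (the assignment runs,
#'   default 100).
#' @param ... Passed to [nmf_factorize()].
#' @return A `cluster_assignment` with `algorithm = "nmf"`.
#' @export
nmf_partition <- function(dataset, gene_set, k, n_init = 100L, seed = 1L,
                          center = "median_center", ...) {
  V <- nmf_input(dataset, gene_set, center)
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- nmf_factorize(V, k, seed = derive_seed(seed, r), ...)
    if (is.null(best) || fit$divergence < best$divergence) best <- fit
  }
  labels <- nmf_assign(best$H)
  names(labels) <- colnames(V)
  if (length(unique(labels)) != k)
    stop("NMF left a metagene without samples for '", dataset$name,
         "' at k=", k)
  cluster_assignment(dataset$name, "nmf", k, labels, seed, best$divergence)
}

# Shared preprocessing for the NMF-based engines.
nmf_input <- function(dataset, gene_set, center) {
  stopifnot(is_expr_dataset(dataset))
  gs <- if (inherits(gene_set, "gene_set")) gene_set$genes else gene_set
  gs <- intersect(gs, genes(dataset))
  if (!length(gs)) stop("gene set empty after restriction to dataset genes")
  ds <- center_genes(subset_dataset(dataset, genes = gs), center)
  nonnegative_fold(ds$values)
}

#' Consensus NMF clustering and its cophenetic correlation
#'
#' Runs `n_runs` seeded NMF factorizations at rank k and averages their
#' sample connectivity matrices (1 where two samples share an argmax
#' metagene) into a consensus matrix of co-clustering frequencies.  The
#' cophenetic correlation of the consensus — the standard rank-selection
#' diagnostic — is the Pearson correlation between the off-diagonal
#' consensus distances (1 - consensus) and the cophenetic (merge-height)
#' distances of an average-linkage tree built on them.
#'
#' @inheritParams kmeans_partition
#' @param n_runs Number of consensus runs (default 10).
#' @param ... Passed to [nmf_factorize()].
#' @return A `consensus_result`: list with `consensus` (samples x samples),
#'   `k`, `n_runs`, `cophenetic` (`NA` when undefined), `cophenetic_defined`,
#'   and `linkage` (the `hclust` tree).
#' @export
consensus_matrix <- function(dataset, gene_set, k, n_runs = 10L, seed = 1L,
                             center = "median_center", ...) {
  if (k < 2L) stop("consensus clustering needs k >= 2")
  if (n_runs < 2L) stop("n_runs must be >= 2")
  V <- nmf_input(dataset, gene_set, center)
  n <- ncol(V)
  C <- matrix(0, n, n, dimnames = list(colnames(V), colnames(V)))
  for (r in seq_len(n_runs)) {
    fit <- nmf_factorize(V, k, seed = derive_seed(seed, 10000L + r), ...)
    lab <- nmf_assign(fit$H)
    C <- C + outer(lab, lab, "==")
  }
  C <- C / n_runs
  coph <- consensus_cophenetic(C)
  structure(list(consensus = C, k = as.integer(k), n_runs = as.integer(n_runs),
                 cophenetic = coph$value, cophenetic_defined = coph$defined,
                 linkage = coph$tree),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k=%d, %d runs, cophenetic %s\n", x$k,
              x$n_runs,
              if (x$cophenetic_defined) sprintf("%.4f", x$cophenetic)
              else "undefined"))
  invisible(x)
}

#' Cophenetic correlation of a consensus matrix
#'
#' @param consensus Symmetric co-clustering frequency matrix with unit
#'   diagonal and entries in `[0, 1]`.
#' @return List with `value` (Pearson correlation, `NA` when undefined),
#'   `defined` (FALSE when the off-diagonal consensus entries have zero
#'   variance, e.g. all runs collapse to one effective cluster), and `tree`
#'   (the average-linkage `hclust` object).
#' @export
consensus_cophenetic <- function(consensus) {
  stopifnot(is.matrix(consensus), isSymmetric(unname(consensus)),
            all(abs(diag(consensus) - 1) < 1e-12))
  d <- stats::as.dist(1 - consensus)
  tree <- stats::hclust(d, method = "average")
  if (stats::var(as.vector(d)) == 0)
    return(list(value = NA_real_, defined = FALSE, tree = tree))
  list(value = stats::cor(as.vector(d), as.vector(stats::cophenetic(tree))),
       defined = TRUE, tree = tree)
}

#' Cophenetic correlation profile over a range of ranks
#'
#' Computes one consensus result per k and reports the profile together with
#' the rank attaining the highest (defined) cophenetic correlation — the
#' heuristic used to judge how many clusters a dataset supports.
#'
#' @inheritParams consensus_matrix
#' @param k_range Integer vector of ranks to profile (default 2:8).
#' @return List with `profile` (named numeric, one value per k; `NA` where
#'   undefined), `best_k`, and `results` (the `consensus_result` per k).
#' @export
cophenetic_profile <- function(dataset, gene_set, k_range = 2:8, n_runs = 10L,
                               seed = 1L, center = "median_center", ...) {
  results <- lapply(k_range, function(k)
    consensus_matrix(dataset, gene_set, k, n_runs = n_runs,
                     seed = derive_seed(seed, 100L * k), center = center, ...))
  names(results) <- as.character(k_range)
  profile <- vapply(results, function(r) r$cophenetic, numeric(1L))
  best_k <- if (all(is.na(profile))) NA_integer_
            else k_range[which.max(profile)]
  list(profile = profile, best_k = best_k, results = results)
}
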