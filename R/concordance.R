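#' Pearson correlation with explicit preconditions
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with nonzero
#'   variance.
#' @return The product-moment correlation.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero-variance input")
  stats::cor(x, y)
}

#' Cluster-by-cluster correlation of two t-score matrices
#'
#' Entry (a, b) is the Pearson correlation between cluster a's moderated-t
#' vector in study A and cluster b's in study B.  Both matrices must be
#' computed over the identical gene universe in identical order; a mismatch
#' is an error, never silently realigned.
#'
#' @param tA,tB `tscore_matrix` objects with equal k.
#' @return k x k numeric correlation matrix (rows = clusters of A).
#' @export
cross_dataset_correlations <- function(tA, tB) {
  stopifnot(inherits(tA, "tscore_matrix"), inherits(tB, "tscore_matrix"))
  if (tA$k != tB$k) stop("t-score matrices have different k")
  if (!identical(rownames(tA$scores), rownames(tB$scores)))
    stop("gene universes differ or are ordered differently")
  stats::cor(tA$scores, tB$scores)
}

# Hungarian algorithm (augmenting paths with potentials) for the minimum-cost
# perfect assignment on an n x n cost matrix.  Returns the column assigned to
# each row.  Column index n+1 plays the role of the virtual start column.
hungarian_min <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)    # row matched to each column (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j]] <- j
  assignment
}

hungarian_max_value <- function(score) {
  if (!nrow(score)) return(0)
  if (nrow(score) == 1L) return(max(score))
  a <- hungarian_min(-score)
  sum(score[cbind(seq_len(nrow(score)), a)])
}

#' Optimal one-to-one matching of clusters across two studies
#'
#' Finds the bijection between row clusters and column clusters maximizing
#' the summed correlation (solved by the Hungarian algorithm).  Among
#' optimal solutions the lexicographically smallest assignment vector is
#' returned, so ties never depend on floating-point traversal order.  The
#' greedy per-row argmax used informally in the literature is available for
#' comparison but can collide labels and is not bijective in general; here it
#' removes each chosen column from play to stay bijective.
#'
#' @param corr Square numeric matrix of cluster-cluster correlations.
#' @param method `"optimal"` (default) or `"greedy"`.
#' @return Integer vector `m` with `m[a]` the column matched to row a.
#' @export
match_clusters <- function(corr, method = c("optimal", "greedy")) {
  method <- match.arg(method)
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("correlation matrix must be square")
  n <- nrow(corr)
  if (method == "greedy") {
    avail <- seq_len(n)
    out <- integer(n)
    for (a in seq_len(n)) {
      b <- avail[which.max(corr[a, avail])]
      out[a] <- b
      avail <- setdiff(avail, b)
    }
    return(out)
  }
  best_total <- hungarian_max_value(corr)
  tol <- 1e-9 * max(1, abs(best_total))
  avail <- seq_len(n)
  out <- integer(n)
  fixed <- 0
  for (a in seq_len(n)) {
    for (b in sort(avail)) {
      rest <- hungarian_max_value(
        corr[seq_len(n) > a, setdiff(avail, b), drop = FALSE])
      if (fixed + corr[a, b] + rest >= best_total - tol) {
        out[a] <- b
        fixed <- fixed + corr[a, b]
        avail <- setdiff(avail, b)
        break
      }
    }
  }
  out
}

#' Cross-study concordance of cluster signatures
#'
#' For every pair of studies, correlates the moderated-t vectors of their
#' clusters, finds the optimal one-to-one matching, and records the matched
#' correlations — the quantities whose ranges summarize how reproducible the
#' subtypes are across populations.
#'
#' @param tscores Named list of `tscore_matrix` objects, all at the same k
#'   and over the same ordered gene universe.
#' @param method Matching method, see [match_clusters()].
#' @return A `concordance_result`: list with `k`, `datasets`, and `pairs`
#'   (per unordered pair: `corr` matrix, `matching`, `matched_correlations`).
#' @export
concordance <- function(tscores, method = "optimal") {
  stopifnot(is.list(tscores), length(tscores) >= 2L)
  nm <- vapply(tscores, function(t) t$dataset_name, character(1L))
  names(tscores) <- nm
  k <- tscores[[1L]]$k
  pairs <- list()
  for (i in seq_len(length(tscores) - 1L)) {
    for (j in seq(i + 1L, length(tscores))) {
      corr <- cross_dataset_correlations(tscores[[i]], tscores[[j]])
      m <- match_clusters(corr, method)
      pairs[[paste(nm[i], nm[j], sep = "|")]] <- list(
        a = nm[i], b = nm[j], corr = corr, matching = m,
        matched_correlations = corr[cbind(seq_len(k), m)])
    }
  }
  structure(list(k = k, datasets = nm, pairs = pairs, method = method),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  mc <- unlist(lapply(x$pairs, `[[`, "matched_correlations"))
  cat(sprintf(
    "concordance_result: k=%d, %d studies, %d pairs, matched r in [%.3f, %.3f]\n",
    x$k, length(x$datasets), length(x$pairs), min(mc), max(mc)))
  invisible(x)
}

#' Propagate reference cluster labels to every study
#'
#' Matches each study's clusters to a reference study's clusters and assigns
#' each cluster the label of its matched reference cluster (e.g. the widely
#' used "mesenchymal-like" / "proliferative-like" names).  The reference
#' keeps its own labels.
#'
#' @param tscores Named list of `tscore_matrix` objects at a common k.
#' @param reference_dataset Name of the reference study (must be present).
#' @param reference_label_map Character vector of length k: label of each
#'   reference cluster index.
#' @param method Matching method, see [match_clusters()].
#' @return Data frame with columns `dataset`, `cluster`, `label`.
#' @export
assign_reference_labels <- function(tscores, reference_dataset,
                                    reference_label_map, method = "optimal") {
  nm <- vapply(tscores, function(t) t$dataset_name, character(1L))
  names(tscores) <- nm
  if (!reference_dataset %in% nm) stop("reference dataset not present")
  k <- tscores[[reference_dataset]]$k
  if (length(reference_label_map) != k)
    stop("reference_label_map must cover clusters 1..k")
  rows <- lapply(nm, function(d) {
    if (d == reference_dataset) {
      lab <- reference_label_map
    } else {
      m <- match_clusters(cross_dataset_correlations(
        tscores[[d]], tscores[[reference_dataset]]), method)
      lab <- reference_label_map[m]
    }
    data.frame(dataset = d, cluster = seq_len(k), label = lab,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ranges of matched correlations per cluster, with exclusions
#'
#' Summarizes a concordance result as the min-max range of matched
#' correlations per cluster over all retained study pairs, with pairs
#' involving excluded (e.g. non-concordant) studies summarized separately
#' against the retained set.  Cluster identity is anchored on a reference
#' study through the pairwise matchings.
#'
#' @param result A `concordance_result`.
#' @param exclude Character vector of study names excluded from the main
#'   ranges.
#' @param reference_dataset Study whose cluster indices anchor cluster
#'   identity (default: the first retained study).
#' @return Data frame with columns `block` (`"retained"` or the excluded
#'   study), `cluster` (reference cluster index), `min`, `max`, `n_pairs`.
#' @export
concordance_summary <- function(result, exclude = character(0L),
                                reference_dataset = NULL) {
  stopifnot(inherits(result, "concordance_result"))
  retained <- setdiff(result$datasets, exclude)
  if (length(retained) < 2L) stop("need at least 2 retained datasets")
  if (is.null(reference_dataset)) reference_dataset <- retained[1L]
  if (!reference_dataset %in% retained)
    stop("reference dataset must be retained")
  k <- result$k

  # map each study's clusters onto the reference's cluster indices
  ref_map <- list()
  ref_map[[reference_dataset]] <- seq_len(k)
  for (d in setdiff(result$datasets, reference_dataset)) {
    key1 <- paste(d, reference_dataset, sep = "|")
    key2 <- paste(reference_dataset, d, sep = "|")
    if (key1 %in% names(result$pairs)) {
      ref_map[[d]] <- result$pairs[[key1]]$matching
    } else {
      m <- result$pairs[[key2]]$matching  # reference cluster -> d cluster
      inv <- integer(k); inv[m] <- seq_len(k)
      ref_map[[d]] <- inv
    }
  }

  rows <- list()
  for (p in result$pairs) {
    ref_cluster <- ref_map[[p$a]]  # identity of each of a's clusters
    block <- if (p$a %in% retained && p$b %in% retained) "retained"
             else if (!(p$a %in% retained) && !(p$b %in% retained)) NA_character_
             else setdiff(c(p$a, p$b), retained)
    if (is.na(block)) next  # excluded-vs-excluded pairs are not summarized
    rows[[length(rows) + 1L]] <- data.frame(
      block = block, cluster = ref_cluster,
      r = p$matched_correlations, stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(long, list(long$block, long$cluster),
                                     drop = TRUE), function(g)
    data.frame(block = g$block[1L], cluster = g$cluster[1L],
               min = min(g$r), max = max(g$r), n_pairs = nrow(g),
               stringsAsFactors = FALSE)))
  agg <- agg[order(agg$block != "retained", agg$block, agg$cluster), ]
  rownames(agg) <- NULL
  agg
}

#' Flag studies whose clusters fail to match any other study
#'
#' A study is non-concordant when its best matched correlation against every
#' other study falls below `threshold`; such studies are the natural
#' candidates for the `exclude` argument of [concordance_summary()].
#'
#' @param result A `concordance_result`.
#' @param threshold Minimum best matched correlation (default 0.3).
#' @return Character vector of non-concordant study names.
#' @export
flag_nonconcordant <- function(result, threshold = 0.3) {
  best <- stats::setNames(rep(-Inf, length(result$datasets)), result$datasets)
  for (p in result$pairs) {
    m <- max(p$matched_correlations)
    best[p$a] <- max(best[p$a], m)
    best[p$b] <- max(best[p$b], m)
  }
  names(best)[best < threshold]
}

#' Cross-tabulate a clustering against previously published labels
#'
#' @param assignment A `cluster_assignment`.
#' @param original_labels Named character vector (names = sample ids) of the
#'   labels assigned by the original study; `NA` or absent samples are
#'   tallied in an `"NC/NA"` column.
#' @return Integer matrix, rows = this pipeline's clusters, columns =
#'   original labels plus `"NC/NA"`.
#' @export
crosstab_assignments <- function(assignment, original_labels) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  ids <- names(assignment$labels)
  orig <- original_labels[ids]
  orig[is.na(orig)] <- "NC/NA"
  lev <- c(sort(setdiff(unique(orig), "NC/NA")), "NC/NA")
  tab <- table(factor(paste0("cluster", assignment$labels),
                      levels = paste0("cluster", seq_len(assignment$k))),
               factor(orig, levels = lev))
  out <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  out
}
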