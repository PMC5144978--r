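#' Gene-shuffling negative control for cross-study concordance
#'
#' Independently permutes every gene within every study (destroying all
#' correlation structure while preserving gene marginals), then reruns the
#' full pipeline — variability-based gene selection, clustering, moderated-t
#' signatures over the full gene universe, and cross-study matching.  Any
#' clustering induces within-study structure even in such data, but matched
#' cross-study correlations should collapse toward zero; their maximum
#' absolute value is the experiment's summary.
#'
#' @param datasets Named list of `expr_dataset` objects on a shared gene
#'   universe.
#' @param k Number of clusters fit to each shuffled study.
#' @param n_per_dataset,statistic Gene selection, see
#'   [select_union_gene_set()].
#' @param algorithm `"kmeans"` (default, fast) or `"nmf"`.
#' @param n_init Restarts for the clustering engine.
#' @param s0_method Fudge-factor rule for the t statistics.
#' @param seed Top-level seed; each study's shuffle and each clustering run
#'   derive their own seed from it.
#' @return A `null_experiment` list: `seed`, `assignments`, `tscores`,
#'   `concordance`, `matched` (all matched correlations), and
#'   `max_abs_matched`.
#' @export
run_null_experiment <- function(datasets, k = 2L, n_per_dataset = 1500L,
                                statistic = "mad", algorithm = "kmeans",
                                n_init = 20L, s0_method = "percentile_grid",
                                seed = 1L) {
  stopifnot(length(datasets) >= 2L)
  shuffled <- lapply(seq_along(datasets), function(i)
    shuffle_within_gene(datasets[[i]], derive_seed(seed, i)))
  names(shuffled) <- vapply(shuffled, function(d) d$name, character(1L))
  gs <- select_union_gene_set(shuffled, n_per_dataset, statistic)
  assignments <- lapply(seq_along(shuffled), function(i) {
    run_seed <- derive_seed(seed, 1000L + i)
    if (algorithm == "kmeans")
      kmeans_partition(shuffled[[i]], gs, k, n_init = n_init, seed = run_seed)
    else
      nmf_partition(shuffled[[i]], gs, k, n_init = n_init, seed = run_seed)
  })
  tscores <- lapply(seq_along(shuffled), function(i)
    moderated_t_matrix(shuffled[[i]], assignments[[i]],
                       s0_method = s0_method))
  conc <- concordance(tscores)
  matched <- unlist(lapply(conc$pairs, `[[`, "matched_correlations"))
  structure(list(seed = seed, assignments = assignments, tscores = tscores,
                 concordance = conc, matched = matched,
                 max_abs_matched = max(abs(matched))),
            class = "null_experiment")
}

#' @export
print.null_experiment <- function(x, ...) {
  cat(sprintf("null_experiment: seed %d, max |matched r| = %.4f over %d pairs\n",
              x$seed, x$max_abs_matched, length(x$concordance$pairs)))
  invisible(x)
}
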