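#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the field's usual
#' defaults: 1500 genes selected per study, k-means with 20 restarts, NMF
#' with 100 assignment initializations and 10 consensus runs, clustering at
#' k = 2..4, cophenetic profiles over k = 2..8.
#'
#' @param datasets Named list of `expr_dataset` objects, or `NULL` when
#'   `dataset_paths` is given.
#' @param dataset_paths,annotation_paths Named character vectors of TSV paths
#'   (names = study identifiers); annotations optional.
#' @param keep_histologies,keep_grades Inclusion filter (NULL skips it).
#' @param n_per_dataset,statistic Gene selection parameters.
#' @param center Pre-clustering per-gene transform.
#' @param algorithms Clustering engines to run.
#' @param k_list Cluster numbers for the main analysis.
#' @param profile_k Ranks profiled for cophenetic diagnostics (NULL skips).
#' @param n_init_kmeans,n_init_nmf,consensus_runs Initialization counts.
#' @param s0_method SAM fudge-factor rule.
#' @param reference_dataset,reference_labels Optional reference study and a
#'   list (keyed by k as character) of its cluster labels.
#' @param exclude_threshold Non-concordance flagging threshold.
#' @param null_replicates Number of gene-shuffling null replicates (0 skips).
#' @param out_dir Output directory.
#' @param seed Top-level seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(datasets = NULL, dataset_paths = NULL,
                            annotation_paths = NULL,
                            keep_histologies = NULL, keep_grades = NULL,
                            n_per_dataset = 1500L, statistic = "mad",
                            center = "median_center",
                            algorithms = c("kmeans", "nmf"),
                            k_list = 2:4, profile_k = 2:8,
                            n_init_kmeans = 20L, n_init_nmf = 100L,
                            consensus_runs = 10L,
                            s0_method = "percentile_grid",
                            reference_dataset = NULL, reference_labels = NULL,
                            exclude_threshold = 0.3, null_replicates = 0L,
                            out_dir = tempfile("run"), seed = 1L) {
  if (is.null(datasets) && is.null(dataset_paths))
    stop("provide either datasets or dataset_paths")
  stopifnot(all(algorithms %in% c("kmeans", "nmf")), all(k_list >= 2L),
            n_per_dataset >= 1L, n_init_kmeans >= 1L, n_init_nmf >= 1L,
            consensus_runs >= 2L)
  structure(as.list(environment()), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full cross-study concordance pipeline
#'
#' Executes ingest, inclusion filtering, gene-universe intersection, union
#' gene selection, per-study clustering with every configured algorithm and
#' k, moderated-t signature summaries, cross-study concordance, cophenetic
#' profiles, and (optionally) the gene-shuffling null — writing every stage's
#' artifacts as plain TSV/JSON under `config$out_dir` together with a
#' manifest sufficient to re-run bit-identically.
#'
#' @param config A [pipeline_config()].
#' @return The output directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  ## ingest
  datasets <- cfg$datasets
  if (is.null(datasets)) {
    datasets <- lapply(names(cfg$dataset_paths), function(nm) {
      ds <- load_expression_matrix(cfg$dataset_paths[[nm]], nm)
      if (!is.null(cfg$annotation_paths) && nm %in% names(cfg$annotation_paths))
        ds <- load_annotations(ds, cfg$annotation_paths[[nm]])
      ds
    })
    names(datasets) <- names(cfg$dataset_paths)
  }
  if (!is.null(cfg$keep_histologies))
    datasets <- lapply(datasets, apply_inclusion_filter,
                       keep_histologies = cfg$keep_histologies,
                       keep_grades = cfg$keep_grades)
  datasets <- intersect_gene_universe(datasets)
  universe <- attr(datasets, "gene_universe")

  ## gene selection
  gs <- select_union_gene_set(datasets, cfg$n_per_dataset, cfg$statistic)
  jsonlite::write_json(
    list(genes = gs$genes, provenance = gs$provenance,
         n_per_dataset = gs$n_per_dataset, statistic = gs$statistic),
    file.path(cfg$out_dir, "gene_set.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("subtypeConcord")),
    seed = cfg$seed, datasets = names(datasets),
    n_samples = vapply(datasets, function(d) ncol(d$values), integer(1L)),
    gene_universe_size = length(universe),
    union_gene_set_size = length(gs$genes),
    parameters = cfg[c("n_per_dataset", "statistic", "center", "algorithms",
                       "k_list", "profile_k", "n_init_kmeans", "n_init_nmf",
                       "consensus_runs", "s0_method", "exclude_threshold",
                       "null_replicates")])

  ## clustering + signatures + concordance per algorithm and k
  assignment_rows <- list()
  for (alg in cfg$algorithms) {
    for (k in cfg$k_list) {
      assignments <- lapply(seq_along(datasets), function(i) {
        run_seed <- derive_seed(cfg$seed, 31L * i + 7L * k +
                                  1e5L * (alg == "nmf"))
        if (alg == "kmeans")
          kmeans_partition(datasets[[i]], gs, k, n_init = cfg$n_init_kmeans,
                           seed = run_seed, center = cfg$center)
        else
          nmf_partition(datasets[[i]], gs, k, n_init = cfg$n_init_nmf,
                        seed = run_seed, center = cfg$center)
      })
      names(assignments) <- names(datasets)
      for (a in assignments)
        assignment_rows[[length(assignment_rows) + 1L]] <- data.frame(
          dataset = a$dataset_name, algorithm = alg, k = k,
          sample_id = names(a$labels), cluster = unname(a$labels),
          stringsAsFactors = FALSE)

      tscores <- lapply(seq_along(datasets), function(i)
        moderated_t_matrix(datasets[[i]], assignments[[i]],
                           gene_universe = universe,
                           s0_method = cfg$s0_method))
      for (t in tscores)
        write_tsv(data.frame(gene = rownames(t$scores), t$scores,
                             check.names = FALSE),
                  file.path(cfg$out_dir, sprintf("tscores_%s_%s_k%d.tsv",
                                                 t$dataset_name, alg, k)))

      conc <- concordance(tscores)
      for (nm in names(conc$pairs)) {
        p <- conc$pairs[[nm]]
        write_tsv(data.frame(cluster = rownames(p$corr), p$corr,
                             check.names = FALSE),
                  file.path(cfg$out_dir, sprintf("corr_%s_%s_%s_k%d.tsv",
                                                 p$a, p$b, alg, k)))
      }
      excl <- flag_nonconcordant(conc, cfg$exclude_threshold)
      if (length(setdiff(conc$datasets, excl)) >= 2L)
        write_tsv(concordance_summary(conc, exclude = excl),
                  file.path(cfg$out_dir,
                            sprintf("concordance_summary_%s_k%d.tsv", alg, k)))
      jsonlite::write_json(
        list(k = k, algorithm = alg, nonconcordant = excl,
             matching = lapply(conc$pairs, function(p)
               list(a = p$a, b = p$b, matching = p$matching,
                    matched_correlations = p$matched_correlations))),
        file.path(cfg$out_dir, sprintf("matching_%s_k%d.json", alg, k)),
        auto_unbox = TRUE, digits = NA)

      if (!is.null(cfg$reference_dataset) &&
          as.character(k) %in% names(cfg$reference_labels)) {
        labels <- assign_reference_labels(
          tscores, cfg$reference_dataset,
          cfg$reference_labels[[as.character(k)]])
        write_tsv(labels, file.path(cfg$out_dir,
                                    sprintf("labels_%s_k%d.tsv", alg, k)))
      }
    }
  }
  write_tsv(do.call(rbind, assignment_rows),
            file.path(cfg$out_dir, "assignments.tsv"))

  ## cophenetic profiles
  if (!is.null(cfg$profile_k)) {
    profiles <- lapply(seq_along(datasets), function(i)
      cophenetic_profile(datasets[[i]], gs, k_range = cfg$profile_k,
                         n_runs = cfg$consensus_runs,
                         seed = derive_seed(cfg$seed, 9000L + i),
                         center = cfg$center))
    names(profiles) <- names(datasets)
    jsonlite::write_json(
      lapply(profiles, function(p)
        list(profile = as.list(p$profile), best_k = p$best_k)),
      file.path(cfg$out_dir, "cophenetic_profiles.json"),
      auto_unbox = TRUE, digits = NA)
    manifest$profile_best_k <- vapply(profiles, function(p) p$best_k,
                                      integer(1L))
  }

  ## gene-shuffling null
  if (cfg$null_replicates > 0L) {
    dir.create(file.path(cfg$out_dir, "null"), showWarnings = FALSE)
    null_summary <- lapply(seq_len(cfg$null_replicates), function(r) {
      ne <- run_null_experiment(datasets, k = min(cfg$k_list),
                                n_per_dataset = cfg$n_per_dataset,
                                statistic = cfg$statistic,
                                n_init = cfg$n_init_kmeans,
                                s0_method = cfg$s0_method,
                                seed = derive_seed(cfg$seed, 5000L + r))
      list(replicate = r, max_abs_matched = ne$max_abs_matched)
    })
    jsonlite::write_json(null_summary,
                         file.path(cfg$out_dir, "null", "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cfg$out_dir)
}

#' Render heatmap figures for a completed run
#'
#' Draws cross-study correlation heatmaps and consensus-ordered heatmaps from
#' a run directory's TSV artifacts.  Rendering requires the pheatmap package
#' and is entirely optional: every quantitative output of the pipeline is
#' already on disk as TSV/JSON.
#'
#' @param run_dir A directory written by [run_pipeline()].
#' @return Character vector of PNG paths written (empty when pheatmap is not
#'   installed).
#' @export
render_reports <- function(run_dir) {
  if (!file.exists(file.path(run_dir, "manifest.json")))
    stop("not a completed run directory: ", run_dir)
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    message("pheatmap not installed; skipping figure rendering")
    return(invisible(character(0L)))
  }
  out <- character(0L)
  for (f in list.files(run_dir, pattern = "^corr_.*\\.tsv$")) {
    m <- utils::read.table(file.path(run_dir, f), sep = "\t", header = TRUE,
                           row.names = 1L, check.names = FALSE)
    png_path <- file.path(run_dir, sub("\\.tsv$", ".png", f))
    grDevices::png(png_path, width = 480, height = 480)
    pheatmap::pheatmap(as.matrix(m), cluster_rows = FALSE,
                       cluster_cols = FALSE, display_numbers = TRUE,
                       main = sub("\\.tsv$", "", f))
    grDevices::dev.off()
    out <- c(out, png_path)
  }
  invisible(out)
}
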