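#' Configuration of the synthetic multi-study generator
#'
#' Defines a population of studies sharing `k_true` subtype expression
#' signatures, observed through study-specific batch effects and gene-wise
#' noise — the statistical structure the concordance pipeline assumes in real
#' multi-cohort transcriptomic data.  An optional contaminant class (a stand-in
#' for serous borderline tumors mixed into high-grade serous cohorts) carries
#' its own disjoint signature and no subtype label.
#'
#' The generative model for gene g, sample j of subtype c, in study d is
#' `x = mu_g + b_dg + gamma_dg * beta * 1[g in S_c] + eps`, with
#' `mu_g ~ N(0,1)` a shared baseline, `b_dg ~ N(0, batch_sd^2)` an additive
#' per-study offset, `log gamma_dg ~ N(0, batch_scale_sd^2)` a multiplicative
#' per-study distortion of the signature effect `beta = effect_size`, and
#' `eps ~ N(0, noise_sd^2)`.
#'
#' @param n_datasets Number of studies.
#' @param samples_per_dataset Tumor (non-contaminant) samples per study.
#' @param n_genes Shared gene-universe size.
#' @param k_true Number of planted subtypes.
#' @param signature_size Genes per subtype signature (disjoint across
#'   subtypes and the contaminant).
#' @param effect_size Mean shift of signature genes in their subtype, in
#'   noise-sd units.
#' @param noise_sd,batch_sd,batch_scale_sd Noise and batch-effect scales.
#' @param subtype_proportions Simplex vector of length `k_true`.
#' @param contaminant_fraction Contaminant samples added per study, as a
#'   fraction of `samples_per_dataset` (0 disables; 0.07 emulates the
#'   observed share of borderline tumors in a mixed cohort).
#' @param contaminant_effect Signature effect size of the contaminant class.
#' @param n_decorrelated Number of trailing studies given private signature
#'   gene sets (their clusters cannot match the shared subtypes; used to
#'   emulate a non-concordant cohort).
#' @param seed Integer seed; identical config and seed give bit-identical
#'   output.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_datasets = 4L, samples_per_dataset = 150L,
                             n_genes = 2000L, k_true = 3L,
                             signature_size = 100L, effect_size = 1.5,
                             noise_sd = 1, batch_sd = 0.5,
                             batch_scale_sd = 0.1,
                             subtype_proportions = rep(1 / k_true, k_true),
                             contaminant_fraction = 0,
                             contaminant_effect = 2,
                             n_decorrelated = 0L, seed = 1L) {
  cfg <- list(n_datasets = as.integer(n_datasets),
              samples_per_dataset = as.integer(samples_per_dataset),
              n_genes = as.integer(n_genes), k_true = as.integer(k_true),
              signature_size = as.integer(signature_size),
              effect_size = effect_size, noise_sd = noise_sd,
              batch_sd = batch_sd, batch_scale_sd = batch_scale_sd,
              subtype_proportions = subtype_proportions,
              contaminant_fraction = contaminant_fraction,
              contaminant_effect = contaminant_effect,
              n_decorrelated = as.integer(n_decorrelated),
              seed = as.integer(seed))
  if (abs(sum(cfg$subtype_proportions) - 1) > 1e-8)
    stop("subtype_proportions must sum to 1")
  if (length(cfg$subtype_proportions) != cfg$k_true)
    stop("subtype_proportions must have length k_true")
  if (cfg$contaminant_fraction < 0 || cfg$contaminant_fraction >= 1)
    stop("contaminant_fraction must lie in [0, 1)")
  if (cfg$samples_per_dataset < 4L * cfg$k_true)
    stop("need at least 4 samples per planted subtype")
  has_cont <- cfg$contaminant_fraction > 0
  need <- cfg$signature_size *
    (cfg$k_true + has_cont + cfg$n_decorrelated * cfg$k_true)
  if (need > cfg$n_genes)
    stop("signature sets do not fit in the gene universe")
  if (cfg$n_decorrelated >= cfg$n_datasets)
    stop("at least one study must carry the shared signatures")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic multi-study expression collection
#'
#' @param config A [synthetic_config()].
#' @return List with `datasets` (list of [expression_dataset()]s whose
#'   annotations carry the planted truth as `original_subtype_label`) and
#'   `truth` (per-study label vectors, signature gene lists, and realized
#'   batch parameters).
#' @export
generate_multistudy <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  mu <- stats::rnorm(cfg$n_genes)
  has_cont <- cfg$contaminant_fraction > 0
  n_cont <- if (has_cont) round(cfg$contaminant_fraction *
                                  cfg$samples_per_dataset) else 0L

  # disjoint signature gene sets: shared subtypes, contaminant, then private
  # sets for each decorrelated study
  pool <- seq_len(cfg$n_genes)
  take <- function(n) { out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out }
  shared_sigs <- lapply(seq_len(cfg$k_true), function(c)
    take(cfg$signature_size))
  cont_sig <- if (has_cont) take(cfg$signature_size) else integer(0L)
  decor_names <- if (cfg$n_decorrelated > 0L)
    sprintf("study%d", seq(cfg$n_datasets - cfg$n_decorrelated + 1L,
                           cfg$n_datasets)) else character(0L)
  private_sigs <- stats::setNames(lapply(decor_names, function(d)
    lapply(seq_len(cfg$k_true), function(c) take(cfg$signature_size))),
    decor_names)

  datasets <- vector("list", cfg$n_datasets)
  truth_labels <- list()
  batch <- list()
  for (d in seq_len(cfg$n_datasets)) {
    nm <- sprintf("study%d", d)
    sigs <- if (nm %in% decor_names) private_sigs[[nm]] else shared_sigs

    counts <- rep(0L, cfg$k_true)
    for (try in seq_len(100L)) {
      counts <- as.integer(stats::rmultinom(1L, cfg$samples_per_dataset,
                                            cfg$subtype_proportions))
      if (all(counts >= 2L)) break
    }
    subtype <- rep(seq_len(cfg$k_true), counts)
    n_tot <- cfg$samples_per_dataset + n_cont
    is_cont <- c(rep(FALSE, cfg$samples_per_dataset), rep(TRUE, n_cont))

    b <- stats::rnorm(cfg$n_genes, sd = cfg$batch_sd)
    gamma <- exp(stats::rnorm(cfg$n_genes, sd = cfg$batch_scale_sd))
    batch[[nm]] <- list(offset = b, scale = gamma)

    x <- matrix(mu + b, cfg$n_genes, n_tot)
    for (j in seq_len(n_tot)) {
      sig <- if (is_cont[j]) cont_sig else sigs[[subtype[min(j, length(subtype))]]]
      eff <- if (is_cont[j]) cfg$contaminant_effect else cfg$effect_size
      x[sig, j] <- x[sig, j] + gamma[sig] * eff * cfg$noise_sd
    }
    x <- x + matrix(stats::rnorm(cfg$n_genes * n_tot, sd = cfg$noise_sd),
                    cfg$n_genes, n_tot)
    dimnames(x) <- list(gene_ids, sprintf("%s_s%03d", nm, seq_len(n_tot)))

    label <- c(paste0("subtype", subtype), rep(NA_character_, n_cont))
    ann <- data.frame(
      sample_id = colnames(x),
      histology = ifelse(is_cont, "borderline", "serous"),
      grade = ifelse(is_cont, "low", "high"),
      stage = "iii",
      original_subtype_label = label,
      stringsAsFactors = FALSE)
    datasets[[d]] <- expression_dataset(nm, x, ann)
    truth_labels[[nm]] <- stats::setNames(label, colnames(x))
  }
  names(datasets) <- vapply(datasets, function(d) d$name, character(1L))
  sig_names <- function(idx) gene_ids[idx]
  truth <- list(
    labels = truth_labels,
    signatures = lapply(shared_sigs, sig_names),
    contaminant_signature = sig_names(cont_sig),
    private_signatures = lapply(private_sigs, function(s)
      lapply(s, sig_names)),
    batch = batch,
    config = cfg)
  list(datasets = datasets, truth = truth)
}

#' Paired clean/contaminated study collections
#'
#' Generates a contaminated collection (with `contaminant_fraction > 0`) and
#' derives the clean arm by removing exactly the contaminant samples, so the
#' two arms are identical in every other draw.  This enables a paired
#' comparison of cophenetic profiles: contaminants form an extra coherent
#' cluster and inflate the apparent support for `k_true + 1` clusters.
#'
#' @param config A [synthetic_config()] with `contaminant_fraction > 0`.
#' @return List with `contaminated` and `clean`, each a
#'   [generate_multistudy()] result.
#' @export
generate_contaminated_pair <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$contaminant_fraction <= 0)
    stop("contaminated arm needs contaminant_fraction > 0")
  contaminated <- generate_multistudy(config)
  clean <- contaminated
  clean$datasets <- lapply(contaminated$datasets, function(ds) {
    keep <- ds$annotations$sample_id[ds$annotations$histology != "borderline"]
    subset_dataset(ds, samples = keep)
  })
  clean$truth$labels <- lapply(clean$truth$labels, function(l) l[!is.na(l)])
  list(contaminated = contaminated, clean = clean)
}
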