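#' Per-gene centering and scaling within a dataset
#'
#' Removes platform location (and optionally scale) effects before
#' clustering.  `median_center` subtracts each gene's median; `zscore`
#' additionally divides by the gene standard deviation, leaving
#' zero-dispersion genes merely centered and recording them in the
#' `zero_sd_genes` attribute; `none` is the identity.
#'
#' @param dataset An `expr_dataset`.
#' @param mode `"median_center"`, `"zscore"` or `"none"`.
#' @return The transformed `expr_dataset`.
#' @export
center_genes <- function(dataset, mode = c("median_center", "zscore", "none")) {
  stopifnot(is_expr_dataset(dataset))
  mode <- match.arg(mode)
  if (mode == "none") return(dataset)
  x <- dataset$values
  x <- x - apply(x, 1L, stats::median)
  flagged <- character(0L)
  if (mode == "zscore") {
    sds <- apply(x, 1L, stats::sd)
    zero <- sds == 0
    flagged <- rownames(x)[zero]
    sds[zero] <- 1
    x <- x / sds
  }
  out <- expression_dataset(dataset$name, x, dataset$annotations)
  attr(out, "zero_sd_genes") <- flagged
  out
}

#' Fold a signed matrix into a nonnegative one
#'
#' NMF requires nonnegative input, but centered expression is signed.  Each
#' gene row g is split into g+ = max(x, 0) and g- = max(-x, 0), doubling the
#' row count; the original matrix is recovered exactly as g+ - g-.
#'
#' @param matrix Numeric genes x samples matrix.
#' @return Nonnegative matrix with `2 * nrow(matrix)` rows; positive parts
#'   first (rownames suffixed `.pos`), negative parts second (`.neg`).
#' @export
nonnegative_fold <- function(matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  pos <- pmax(matrix, 0)
  neg <- pmax(-matrix, 0)
  rn <- rownames(matrix)
  if (!is.null(rn)) {
    rownames(pos) <- paste0(rn, ".pos")
    rownames(neg) <- paste0(rn, ".neg")
  }
  rbind(pos, neg)
}

#' Shuffle each gene's values across samples
#'
#' The structure-destroying negative control: every gene row is permuted
#' independently across samples with a seeded generator, so all gene-level
#' marginals (mean, variance, MAD) are preserved exactly while inter-gene and
#' sample correlation structure is destroyed.  Annotations are untouched.
#'
#' @param dataset An `expr_dataset`.
#' @param seed Integer seed controlling all permutations.
#' @return The shuffled `expr_dataset`.
#' @export
shuffle_within_gene <- function(dataset, seed) {
  stopifnot(is_expr_dataset(dataset))
  x <- dataset$values
  n <- ncol(x)
  if (n > 1L) {
    set.seed(as.integer(seed))
    for (i in seq_len(nrow(x)))
      x[i, ] <- x[i, sample.int(n)]
  }
  expression_dataset(dataset$name, x, dataset$annotations)
}

# Deterministic expansion of one top-level seed into per-run seeds.
# Kept below 2^31 so the result is always a valid R integer.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %%
               2147483647)
}
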