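# Small synthetic fixtures shared across test files.  Sizes are kept well
# below the analysis defaults so the unit suite stays fast; the acceptance
# tests run the full default configuration.

small_config <- function(seed = 1L, ...) {
  args <- list(n_datasets = 2L, samples_per_dataset = 60L, n_genes = 500L,
               k_true = 3L, signature_size = 40L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_multistudy(small_config())
    cache
  }
})

# deterministic toy dataset with known numbers
toy_dataset <- function(name = "toy") {
  values <- matrix(c(1, 2, 3, 4, 100,
                     5, 5, 5, 5, 5,
                     2, 4, 6, 8, 10), nrow = 3L, byrow = TRUE,
                   dimnames = list(c("gA", "gB", "gC"),
                                   paste0("s", 1:5)))
  expression_dataset(name, values)
}

# adjusted Rand index between two labelings over the same samples
ari <- function(a, b) {
  stopifnot(requireNamespace("mclust", quietly = TRUE))
  ids <- intersect(names(a), names(b))
  mclust::adjustedRandIndex(a[ids], b[ids])
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
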