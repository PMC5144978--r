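#!/usr/bin/env Rscript
# Generate the default synthetic multi-study collection (4 studies x 150
# samples x 2000 genes, 3 planted subtypes with shared signatures and
# study-specific batch effects) and write it in the TSV format the ingest
# stage reads.  Downstream drivers consume these files, mirroring how the
# real analysis consumes preprocessed expression matrices.

library(subtypeConcord)

seed <- 1L
out <- "scratch/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- generate_multistudy(synthetic_config(seed = seed))
for (ds in sim$datasets) {
  write_expression_matrix(ds, file.path(out, paste0(ds$name, ".tsv")))
  write_annotations(ds, file.path(out, paste0(ds$name, "_annotations.tsv")))
}
saveRDS(sim$truth, file.path(out, "truth.rds"))  # scratch only, not shipped

cat("wrote", length(sim$datasets), "studies to", out, "\n")
for (ds in sim$datasets)
  cat(sprintf("  %s: %d genes x %d samples, subtype counts %s\n",
              ds$name, nrow(ds$values), ncol(ds$values),
              paste(table(sim$truth$labels[[ds$name]]), collapse = "/")))
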