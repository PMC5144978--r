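#!/usr/bin/env Rscript
# External-data replication driver (not run in CI: it needs the five real
# cohort matrices, which must be obtained and preprocessed separately).
#
# Usage:
#   Rscript analysis/07_external_replication.R <dir>
#
# <dir> must contain, per study S in {tcga, mayo, yoshihara, tothill, bonome}:
#   S.tsv               genes x samples log-expression (TSV, header = samples)
#   S_annotations.tsv   sample_id / histology / grade [/ stage / label]
#
# With those inputs the driver reports the quantities the real analysis
# prints: per-study analytic sample counts after restricting to high-grade
# serous and high-grade endometrioid tumors (borderline/LMP excluded; for
# Tothill this removes the 18 borderline samples), the size of the shared
# gene universe (10,930 genes on the published cohorts), and the union of
# each study's 1500 most variable genes (3698 genes).

library(subtypeConcord)

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) stop("usage: 07_external_replication.R <data-dir>")
dir <- args[[1L]]
studies <- c("tcga", "mayo", "yoshihara", "tothill", "bonome")
paths <- file.path(dir, paste0(studies, ".tsv"))
if (!all(file.exists(paths)))
  stop("missing expression matrices under ", dir)

aliases <- c(lmp = "borderline", `low malignant potential` = "borderline",
             `grade 3` = "high", `grade 2` = "high", g2 = "high", g3 = "high")

datasets <- lapply(studies, function(s) {
  ds <- load_expression_matrix(file.path(dir, paste0(s, ".tsv")), s)
  ds <- load_annotations(ds, file.path(dir, paste0(s, "_annotations.tsv")),
                         aliases = aliases)
  filtered <- apply_inclusion_filter(ds, c("serous", "endometrioid"), "high")
  rep <- attr(filtered, "filter_report")
  cat(sprintf("%s: %d -> %d samples (histology excl. %d, grade excl. %d, missing %d)\n",
              s, rep$n_in, rep$n_kept, rep$n_excluded_histology,
              rep$n_excluded_grade, rep$n_excluded_missing))
  filtered
})

datasets <- intersect_gene_universe(datasets)
cat("shared gene universe:", attr(datasets, "gene_universe_size"), "genes\n")
gs <- select_union_gene_set(datasets, n_per_dataset = 1500L)
cat("union of per-study top-1500 variable genes:", length(gs$genes), "\n")
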