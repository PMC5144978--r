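#!/usr/bin/env Rscript
# Summary tables from the completed run: matched-correlation ranges per
# cluster and k (the cross-study concordance table) and cross-tabulations of
# our assignments against the planted subtype labels.

library(subtypeConcord)

run_dir <- "results/run"
if (!file.exists(file.path(run_dir, "manifest.json")))
  stop("run analysis/02_pipeline.R first")
dir.create("results/tables", showWarnings = FALSE)

## matched-correlation ranges per algorithm and k (already computed by the
## pipeline; gathered into one table here)
rows <- list()
for (alg in c("kmeans", "nmf")) for (k in 2:4) {
  f <- file.path(run_dir, sprintf("concordance_summary_%s_k%d.tsv", alg, k))
  if (!file.exists(f)) next
  s <- read.delim(f)
  s$algorithm <- alg
  s$k <- k
  rows[[length(rows) + 1L]] <- s
}
ranges <- do.call(rbind, rows)
write.table(ranges, "results/tables/matched_correlation_ranges.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("matched-correlation ranges (retained studies):\n")
print(subset(ranges, block == "retained",
             select = c(algorithm, k, cluster, min, max)), row.names = FALSE)

## cross-tabulation of k-means assignments vs. planted labels, per study
truth <- readRDS("scratch/data/truth.rds")
assignments <- read.delim(file.path(run_dir, "assignments.tsv"))
for (kk in 2:4) {
  for (study in unique(assignments$dataset)) {
    sel <- assignments[assignments$dataset == study &
                         assignments$algorithm == "kmeans" &
                         assignments$k == kk, ]
    a <- cluster_assignment(study, "kmeans", kk,
                            setNames(sel$cluster, sel$sample_id), 1L, NA_real_)
    tab <- crosstab_assignments(a, truth$labels[[study]])
    write.table(cbind(cluster = rownames(tab), as.data.frame.matrix(tab)),
                sprintf("results/tables/crosstab_%s_k%d.tsv", study, kk),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
cat("\nexample cross-tabulation (study1, k = 3):\n")
print(read.delim("results/tables/crosstab_study1_k3.tsv"), row.names = FALSE)
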