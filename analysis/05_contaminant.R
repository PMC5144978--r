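#!/usr/bin/env Rscript
# Paired clean/contaminated experiment: does mixing a small distinct
# contaminant class (7% of samples, emulating serous borderline tumors in a
# high-grade serous cohort) inflate the cophenetic support for one extra
# cluster?  Compares cophenetic(k_true + 1) - cophenetic(k_true) between the
# two arms over seeded replicates.

library(subtypeConcord)

n_seeds <- 10L
rows <- lapply(seq_len(n_seeds), function(s) {
  pair <- generate_contaminated_pair(synthetic_config(
    n_datasets = 1L, contaminant_fraction = 0.07, seed = s))
  prof <- lapply(pair, function(arm) {
    gs <- select_union_gene_set(arm$datasets, n_per_dataset = 150L)
    cophenetic_profile(arm$datasets[[1L]], gs, k_range = 3:4, n_runs = 10L,
                       seed = 100L + s)$profile
  })
  data.frame(seed = s,
             clean_k3 = prof$clean[["3"]], clean_k4 = prof$clean[["4"]],
             cont_k3 = prof$contaminated[["3"]],
             cont_k4 = prof$contaminated[["4"]])
})
tab <- do.call(rbind, rows)
tab$clean_diff <- tab$clean_k4 - tab$clean_k3
tab$cont_diff <- tab$cont_k4 - tab$cont_k3
tab$inflated <- tab$cont_diff > tab$clean_diff
dir.create("results", showWarnings = FALSE)
write.table(format(tab, digits = 5), "results/contaminant_profiles.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(tab[, c("seed", "clean_diff", "cont_diff", "inflated")],
      row.names = FALSE, digits = 3)
cat(sprintf("contaminated arm favors k = 4 more than the clean arm in %d/%d seeds\n",
            sum(tab$inflated), n_seeds))
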