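# subtypeConcord

Unsupervised molecular subtypes of high-grade serous ovarian cancer (HGSC)
have been reported at k = 4 in several cohorts, yet the supporting heuristics
are fragile: any clustering algorithm induces structure *within* a dataset,
so the meaningful question is whether the same subtypes reappear *across*
independent populations. `subtypeConcord` implements a cross-study
concordance pipeline for exactly this question, for anyone comparing
expression-based tumor subtypes across cohorts:

1. **Independent clustering per study** — best-of-N Euclidean k-means
   (20 seeded restarts) and consensus nonnegative matrix factorization
   (Brunet multiplicative updates minimizing generalized Kullback–Leibler
   divergence on the positive/negative fold of centered expression), with
   cophenetic correlation profiles over k = 2..8 as the rank diagnostic.
2. **Cluster signatures** — each cluster is summarized as a vector of SAM
   moderated t statistics over the full shared gene universe,
   d_i = (x̄₁ − x̄₂) / (s_i + s₀), one-vs-rest, with the Tusher/Chu
   percentile-grid estimate of the fudge factor s₀.
3. **Cross-study matching** — Pearson correlations between signature vectors
   of every cluster pair across studies, with the optimal one-to-one matching
   found by the Hungarian algorithm; matched-correlation ranges summarize the
   evidence per cluster and k, and reference labels (e.g. "mesenchymal-like")
   propagate through the matching.
4. **Negative control** — shuffling each gene independently within each study
   destroys cross-study structure while preserving gene marginals; matched
   cross-study correlations must collapse toward 0 (≈ 2/√n_genes) even though
   within-study k = 2 antisymmetry persists exactly.
5. **Synthetic multi-study generator** — shared subtype signatures,
   study-specific additive/multiplicative batch effects, gene-wise noise, and
   an optional contaminant class (emulating serous borderline tumors, ~7% of
   a mixed cohort) that demonstrably inflates the cophenetic support for one
   extra cluster.

## Worked example

```r
library(subtypeConcord)

sim <- generate_multistudy(synthetic_config(seed = 1))   # 4 studies, k_true = 3
gs  <- select_union_gene_set(sim$datasets, n_per_dataset = 150)

tsc <- lapply(sim$datasets, function(ds) {
  a <- kmeans_partition(ds, gs, k = 3, n_init = 20, seed = 1)
  moderated_t_matrix(ds, a)
})
concordance(tsc)
#> concordance_result: k=3, 4 studies, 6 pairs, matched r in [0.820, 0.850]

cophenetic_profile(sim$datasets[[1]], gs, k_range = 2:6, n_runs = 10, seed = 5)$profile
#>         2         3         4         5         6
#> 0.9949896 1.0000000 0.9969457 0.9890965 0.9839595
```

Matched cross-study correlations above 0.8 for every cluster pair, and a
cophenetic profile peaking at the planted k = 3: the two readouts that, on
real cohorts, distinguish reproducible subtypes from clustering artifacts.
The numbered drivers under `analysis/` run the complete workflow
(`01_simulate` → `02_pipeline` → `03_tables` → `04_null` →
`05_contaminant` → `06_figures`), writing all tables under `results/`;
`analysis/07_external_replication.R` is the driver for user-supplied real
cohort matrices.

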