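---
title: "Cross-study concordance of expression subtypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study concordance of expression subtypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtypeConcord)
```

## The problem and the approach

Clustering a single expression cohort always produces clusters, and
within-cohort diagnostics (consensus heatmaps, cophenetic correlations)
always show *some* structure — any partitioning algorithm induces it. The
question that matters for tumor subtyping is whether independently clustered
cohorts yield the *same* subtypes. `subtypeConcord` operationalizes that
question in four steps: cluster each study independently, summarize each
cluster as a differential-expression signature over a shared gene universe,
correlate signatures across studies, and compare the observed concordance to
a randomization null. Pooled clustering of concatenated cohorts is
deliberately avoided: it confounds subtype structure with platform and
population differences, which is why no cross-study batch correction is
offered either.

## Models and procedures

### Gene selection

Within each study, genes are ranked by dispersion — by default the median
absolute deviation about the gene median scaled by 1.4826 (so it estimates
the standard deviation under normality), with unbiased variance as the
alternative — and each study's top `n_per_dataset` genes (default 1500) are
pooled into a union set used for clustering. MAD is the default because it is
robust to the heavy-tailed outliers common in microarray data; on clean data
the two rankings agree closely and both are retained as options. Ties at the
selection boundary break lexicographically, so selection is deterministic
under any input ordering.

### k-means

Samples are observations in the union-gene, per-gene median-centered space
(median centering removes platform location effects without touching
dispersion ranks, which is why it is the default over z-scoring or no
transform). `stats::kmeans` is run from `n_init = 20` seeded random starts
(initial centers drawn as k distinct samples) and the solution with the
lowest within-cluster sum of squares is kept; a run that empties a cluster
is discarded and redrawn up to five times the restart budget, preserving the
every-cluster-nonempty invariant without biasing toward small k. `k` equal
to the sample count is returned directly as the exact singleton solution.

### Consensus NMF and the cophenetic diagnostic

Centered expression is signed, so each gene row x is folded into
(max(x, 0), max(−x, 0)), doubling the rows while preserving x exactly as
their difference — the standard device for applying NMF to centered
expression. Factorization uses multiplicative updates minimizing the
generalized Kullback–Leibler divergence from a seeded uniform random
initialization; the divergence is provably non-increasing per update, and the
test suite audits this on a tracked trace. Iteration stops when the sample
assignments (argmax over metagene coefficients, ties to the lowest index)
are stable for 4 consecutive checks spaced 10 iterations apart, when the
relative divergence change falls below `tol = 1e-6`, or at
`max_iter = 1000` — the assignment-stability rule is the natural criterion
when the factorization is used only for partitioning.

For rank selection, `n_runs = 10` factorizations per k are reduced to a
consensus matrix of co-clustering frequencies (entries are exact multiples of
1/n_runs; symmetry and the unit diagonal hold by construction). The
cophenetic correlation is the Pearson correlation between the off-diagonal
consensus distances (1 − consensus) and the merge-height distances of an
average-linkage tree built on them; average linkage is the convention of the
NMF literature this diagnostic comes from. A consensus with zero off-diagonal
variance (all runs collapse to one effective cluster) has no defined
cophenetic value and is reported as an explicit undefined marker, never a
silent number. Profiles run over k = 2..8 by default; the argmax is reported
but the full profile is the real diagnostic, since values near saturation
differ only in the third decimal.

### SAM moderated t signatures

Each cluster is contrasted one-vs-rest within its own study:
d_i = (mean difference) / (pooled SE + s₀) per gene, over the full shared
gene universe (the union subset is a config switch). One-vs-rest is the only
contrast that yields exactly one vector per cluster; at k = 2 the two columns
are exact negations, an identity the tests assert. The fudge factor s₀
follows the Tusher/Chu percentile-grid recipe — candidates at the 0, 5, …,
100th percentiles of the pooled SEs, choosing the candidate minimizing the
coefficient of variation of windowed MADs of d across 100 SE-quantile
windows — estimated once per contrast; a fixed-percentile shortcut and a
user-supplied s₀ (including 0, the plain pooled t) are available. A gene with
exactly equal group means scores 0 regardless of s₀. No false-discovery
machinery is attached: the signature vector itself, not significance calls,
feeds the concordance stage.

### Matching and summaries

Cluster–cluster Pearson correlations between two studies' signature matrices
require identical gene order; a mismatch is an error, never a silent
realignment. The one-to-one matching maximizes the summed correlation via the
Hungarian algorithm — a greedy per-cluster argmax can collide labels and is
kept only as a comparison option — and among equally optimal bijections the
lexicographically smallest is returned (tolerance 1e-9), making ties
deterministic. Matched-correlation ranges per cluster are tabulated with
cluster identity anchored on a reference study through the pairwise
matchings; studies whose best matched correlation falls below 0.3 are flagged
non-concordant and summarized separately rather than silently dropped, and
reference labels propagate to every study through its matching to the
reference. Cross-k correspondence within a study uses the same correlation
matching applied across its own k's.

### Randomization null

Each gene's values are permuted independently within each study, preserving
all gene marginals. The full pipeline is rerun on the shuffled data. Matched
cross-study correlations between independent signature vectors of length
n_genes concentrate near 0 with spread of order 1/√n_genes, so at a
10,000-gene universe the maximum |matched r| is expected (and asserted) to
stay below 0.1, while at 500 genes only a loose 0.5 bound is meaningful —
both bounds are empirically calibrated test thresholds, not model constants.
Within-study k = 2 antisymmetry persists exactly on shuffled data, which is
precisely the point: within-study structure is induced by clustering,
cross-study structure is not.

## The synthetic generator

`generate_multistudy()` draws, for gene g and sample j of subtype c in study
d:

x = μ_g + b_dg + γ_dg · β · 1[g ∈ S_c] + ε,

with μ_g ~ N(0,1) a shared baseline, b_dg ~ N(0, batch_sd²) an additive
study offset, log γ_dg ~ N(0, batch_scale_sd²) a multiplicative distortion of
the signature effect β, and ε ~ N(0, noise_sd²). Defaults — 4 studies × 150
samples × 2000 genes, k_true = 3, 100 genes per disjoint signature,
β = 1.5 noise-sd units, batch_sd = 0.5, batch_scale_sd = 0.1 — emulate
multi-cohort microarray data: location/scale platform differences between
studies, subtype effects large enough that clustering is informative but far
from noiseless. Disjoint signatures keep ground-truth matching unambiguous
for oracle tests. The optional contaminant class (default fraction 0.07 when
enabled, matching the observed share of borderline tumors in a mixed cohort
of 260; effect size 2.0, reflecting its markedly distinct profile) carries
its own signature and no subtype label; `generate_contaminated_pair()`
returns a contaminated collection and the identical collection with
contaminants removed, enabling the paired cophenetic comparison. A
`n_decorrelated` option gives trailing studies private signatures to emulate
a cohort whose clusters cannot match anyone else's.

What the generator does *not* emulate: probe-level artifacts, correlated or
overlapping signatures, non-Gaussian noise, copy-number-driven expression,
and survival structure. Tests passing on this generator therefore show that
the pipeline recovers planted structure under idealized multi-study
conditions and that its negative control collapses as theory predicts — not
that any particular real cohort has two, three, or four subtypes.

## Problem sizes and seeds

Desk-scale runs select 150 genes per study on the 2000-gene synthetic
universe (the 1500-gene default is proportioned to the ~11,000-gene universe
of real cross-platform cohorts) and use 3 NMF assignment initializations,
since the synthetic optima are well separated; consensus runs stay at 10, the
value the cophenetic diagnostic is defined over. Unit tests use an even
smaller 2-study, 500-gene configuration. All randomness flows from one
top-level seed expanded into per-run seeds by a fixed affine counter scheme
(`derive_seed`), so every table is bit-reproducible; the pipeline writes a
manifest (seeds, parameters, counts) with every run, and rerunning a config
reproduces every artifact byte-for-byte.

## Known limitations

- The cophenetic argmax on well-separated synthetic data saturates near 1.0,
  so rank selection there hinges on third-decimal differences; on real data
  the profiles are far from saturation and the diagnostic is more
  discriminating. The acceptance checks therefore use a majority-of-seeds
  rule rather than a per-seed assertion.
- The Hungarian matching is exact but assumes a square correlation matrix;
  comparing clusterings with different k is handled by the cross-k matching
  convention, not by partial assignment.
- The SAM s₀ grid follows the published recipe, but equivalence to any
  specific historical implementation's tie-breaking is not asserted.
- Ingest consumes preprocessed log-scale matrices only; normalization and
  probe-to-gene mapping are upstream concerns by design.
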