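Package: subtypeConcord
Title: Cross-Study Concordance of Molecular Tumor Subtypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clusters each expression study independently (best-of-N k-means
    and consensus nonnegative matrix factorization with cophenetic rank
    diagnostics), summarizes every cluster as a vector of SAM moderated
    t statistics over a shared gene universe, matches clusters across studies
    by optimal one-to-one Pearson-correlation assignment, and assesses the
    evidence with a gene-wise shuffling null.  A synthetic multi-study
    generator with shared subtype signatures, study-specific batch effects,
    and an optional contaminant cluster (emulating serous borderline tumors
    in high-grade serous ovarian cancer cohorts) makes every stage testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
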