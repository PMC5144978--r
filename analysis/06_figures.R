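#!/usr/bin/env Rscript
# Optional heatmap rendering for the completed run (requires pheatmap).
# Every quantitative result is already on disk as TSV/JSON; these figures
# are the cross-study correlation panels.

library(subtypeConcord)

paths <- render_reports("results/run")
if (length(paths)) cat("wrote", length(paths), "heatmaps under results/run\n")
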