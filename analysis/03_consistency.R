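#!/usr/bin/env Rscript
# Stage 3 — apply the conservative sign-consistency model: every (edge,
# contrast) pair is checked for a definite contradiction between the two
# endpoint labels and the edge's role. Reports the global load, the mean
# per-edge inconsistency (mEdge), and the counts split by role and by
# single-regulator targets.

suppressPackageStartupMessages(library(grnsign))

net <- read_edge_list("results/world/network.tsv")
lab_df <- utils::read.delim("results/labels.tsv", check.names = FALSE)
labels <- as.matrix(lab_df[, -1L])
rownames(labels) <- lab_df$gene
storage.mode(labels) <- "integer"

report <- assess(net, labels)
print(report)
cat("splits:\n")
print(report$splits)

write_report_tables(report, "results/edges.tsv", "results/contrasts.tsv")
jsonlite::write_json(
  list(global = report$global, nPairs = report$nPairs, mEdge = report$mEdge,
       splits = as.list(report$splits),
       dropped_genes = length(report$dropped$genes)),
  "results/consistency.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("written: results/edges.tsv, results/contrasts.tsv,",
    "results/consistency.json\n")
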