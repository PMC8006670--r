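#!/usr/bin/env Rscript
# Stage 2 — normalize the compendium (per-dataset quantile normalization,
# then per-dataset z-scoring), compute case-vs-reference contrasts,
# calibrate the deregulation threshold at the 50% target fraction (with the
# 1/3 and 2/3 sensitivity settings), and write the ternary label matrix.

suppressPackageStartupMessages(library(grnsign))

comp <- read_compendium("results/world/expression.tsv",
                        "results/world/samples.tsv")
defs <- read_contrasts("results/world/contrasts.tsv")

comp <- zscore_by_dataset(quantile_normalize(comp))
cm <- compute_contrasts(comp, defs)

cals <- lapply(c(third = 1 / 3, half = 0.5, two_thirds = 2 / 3),
               function(f) calibrate_threshold(cm, f))
for (nm in names(cals)) print(cals[[nm]])

labels <- label_genes(cm, cals$half)
dir.create("results", showWarnings = FALSE)
utils::write.table(
  data.frame(gene = rownames(labels), labels, check.names = FALSE),
  "results/labels.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  lapply(cals, function(x) list(t = x$t, target_fraction = x$target_fraction,
                                achieved_fraction = x$achieved_fraction)),
  "results/calibration.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("labelled %d of %d gene x contrast entries as deregulated\n",
            sum(labels != 0L), length(labels)))
cat("written: results/labels.tsv, results/calibration.json\n")
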