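#!/usr/bin/env Rscript
# Stage 1 — generate the study's synthetic world: a signed regulatory
# network with coherent path signs, and a three-dataset expression
# compendium driven by it (wild-type references plus knockout,
# overexpression, stress and extra wild-type case groups).
#
# Writes results/world/{network,expression,samples,contrasts,ground_truth}.tsv
# and config.json — the exact files every later stage consumes.

suppressPackageStartupMessages(library(grnsign))

seed <- 1L
cfg <- simulation_config(seed = seed)
world <- synthetic_world(cfg)
write_world(world, "results/world")

cat("Synthetic world (seed", seed, ")\n")
print(world)
print(world$network)
cat("smallest nonzero noiseless |delta|:", round(world$min_delta0, 3), "\n")
cat("condition groups:\n")
print(table(world$conditions$type))
cat("written to results/world/\n")
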