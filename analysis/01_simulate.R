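#!/usr/bin/env Rscript
# Step 1: generate the synthetic study dataset.
#
# Emulates the study design this pipeline targets: 19 early-stage and 18
# late-stage tumor samples against 24 adjacent-normal samples over a sparse
# protein-interaction module (50 proteins, mean degree 3), with 20% of true
# interactions rewired in each cancer stage and a candidate edge list
# contaminated with 20% false-positive interactions. Writes the plain-text
# dataset under results/synthetic_data/.

library(crvnet)

cfg <- simulation_config(seed = 20260921L)
ds <- generate_dataset(cfg)
paths <- write_dataset(ds, "results/synthetic_data")

print(ds)
cat("true edges (normal):",
    sum(ds$networks$normal[upper.tri(ds$networks$normal)] != 0), "\n")
cat("candidate edges written:", nrow(ds$candidate_edges),
    "->", paths[["candidate_edges"]], "\n")
cat("differential (truth) proteins: early", length(ds$truth$early),
    "| late", length(ds$truth$late), "\n")
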