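#!/usr/bin/env Rscript
# Step 3: regression-based identification of the refined interaction
# matrices.
#
# For each pool protein, fits the linear association model on z-scored
# samples of one condition (no-intercept least squares = Gaussian MLE),
# selects the model order by AIC over correlation-ranked nested models,
# prunes coefficients by two-sided t-test (p < 0.05), and assembles the
# symmetric refined matrix per condition: one noncancer network (NPPIN),
# and cancer networks (CPPINs) for the early, late and pooled (total)
# stages. Writes one weighted edge table per network under
# results/networks/.

library(crvnet)

expr <- read_expression("results/synthetic_data/expression.tsv")
sheet <- read_sample_sheet("results/synthetic_data/sample_sheet.tsv", expr)
ppi <- read_ppi_edges("results/synthetic_data/candidate_edges.tsv",
                      c("protein_a", "protein_b"))
pool <- utils::read.delim("results/pool/pool.tsv")

candidate <- build_candidate_network(pool, ppi)
cat("candidate network:", igraph::vcount(candidate), "proteins,",
    igraph::ecount(candidate), "edges\n")

groups <- list(
  normal = sheet$sample_id[sheet$condition == "normal"],
  early = sheet$sample_id[sheet$stage == "early"],
  late = sheet$sample_id[sheet$stage == "late"],
  total = sheet$sample_id[sheet$condition == "cancer"]
)

dir.create("results/networks", showWarnings = FALSE, recursive = TRUE)
for (cond in names(groups)) {
  Z <- z_transform(expr, groups[[cond]])
  A <- identify_network(Z, candidate, t_alpha = 0.05, condition = cond)
  edges <- matrix_to_edges(A, "alpha")
  crvnet:::write_tsv(edges, file.path("results/networks",
                                      paste0("network_", cond, ".tsv")))
  cat(sprintf("%-6s: %3d samples -> %3d retained interactions\n",
              cond, length(groups[[cond]]), nrow(edges)))
}
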