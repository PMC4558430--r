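#!/usr/bin/env Rscript
# Step 5: evaluate the recovered networks and markers against the
# generator's ground truth.
#
# Reports edge-support precision/recall/F1 per condition and the AUC with
# which CRV ranks truly rewired proteins above unperturbed ones, and writes
# results/evaluation.tsv.

library(crvnet)

truth <- read_dataset("results/synthetic_data")
pool <- utils::read.delim("results/pool/pool.tsv")
ppi <- truth$candidate_edges
candidate <- build_candidate_network(pool, ppi)
prot <- igraph::V(candidate)$name

read_net <- function(cond) {
  edges_to_matrix(utils::read.delim(
    file.path("results/networks", paste0("network_", cond, ".tsv"))),
    prot, "alpha")
}

support_stats <- function(A_hat, A_true) {
  A_true <- A_true[prot, prot]
  ph <- A_hat[upper.tri(A_hat)] != 0
  pt_ <- A_true[upper.tri(A_true)] != 0
  tp <- sum(ph & pt_)
  prec <- if (sum(ph)) tp / sum(ph) else NA_real_
  rec <- if (sum(pt_)) tp / sum(pt_) else NA_real_
  c(precision = prec, recall = rec,
    f1 = if (tp) 2 * prec * rec / (prec + rec) else 0)
}

rank_auc <- function(score, positives) {
  pos <- score[names(score) %in% positives]
  neg <- score[!names(score) %in% positives]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

A_normal <- read_net("normal")
rows <- NULL
for (cond in c("normal", "early", "late")) {
  st <- support_stats(read_net(cond), truth$networks[[cond]])
  row <- data.frame(condition = cond, t(st))
  if (cond != "normal") {
    nt <- utils::read.delim(file.path("results/markers",
                                      paste0("node_table_", cond, ".tsv")))
    crv <- stats::setNames(nt$crv, nt$protein)
    row$marker_auc <- rank_auc(crv, truth$truth[[cond]])
  } else {
    row$marker_auc <- NA_real_
  }
  rows <- rbind(rows, row)
}
crvnet:::write_tsv(rows, "results/evaluation.tsv")
print(rows, digits = 3)
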