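# Shared fixtures and small oracles, all built in code at test time.

# A small, fast simulation configuration for structural tests;
# any argument can be overridden.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_proteins = 20L, n_early = 15L, n_late = 15L, n_normal = 15L,
         mean_degree = 2, seed = 42L),
    list(...))
  do.call(simulation_config, args)
}

# Rank-based AUC (Wilcoxon formula): probability that a positive outranks
# a negative, ties counted half.
rank_auc <- function(score, positives) {
  pos <- score[names(score) %in% positives]
  neg <- score[!names(score) %in% positives]
  if (!length(pos) || !length(neg)) return(NA_real_)
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# F1 of nonzero-support recovery between two symmetric matrices.
support_f1 <- function(A_hat, A_true) {
  ph <- A_hat[upper.tri(A_hat)] != 0
  pt_ <- A_true[upper.tri(A_true)] != 0
  tp <- sum(ph & pt_)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + sum(ph & !pt_) + sum(!ph & pt_))
}

# Named symmetric matrix from a flat upper-triangle specification.
sym_matrix <- function(nodes, ...) {
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (e in list(...)) {  # each e = c(i, j, value)
    A[e[[1]], e[[2]]] <- A[e[[2]], e[[1]]] <- as.numeric(e[[3]])
  }
  A
}

write_tmp_tsv <- function(lines, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = envir)
  writeLines(lines, path)
  path
}
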