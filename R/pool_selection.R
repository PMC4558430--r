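# Normalization and differential-protein pool selection: per-gene z-scores,
# a two-group ANOVA screen with Bonferroni control, and one-hop PPI closure.

#' Z-transform expression per gene
#'
#' Each gene row is centered and scaled to sample mean 0 and sample standard
#' deviation 1 (denominator n - 1) across the given sample group. Genes with
#' zero variance map to all-zero rows and are flagged in the
#' `zero_variance` attribute.
#'
#' @param expr genes x samples numeric matrix.
#' @param samples Sample ids (columns) defining the group; defaults to all.
#' @return genes x group matrix of z-scores with attribute `zero_variance`
#'   (named logical).
#' @export
z_transform <- function(expr, samples = colnames(expr)) {
  if (length(samples) == 0L) stop("sample group is empty")
  miss <- setdiff(samples, colnames(expr))
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  if (length(samples) < 2L) {
    stop("z-transform needs at least 2 samples (sd is undefined for 1)")
  }
  x <- expr[, samples, drop = FALSE]
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  zero <- sdv == 0 | is.na(sdv)
  z <- (x - mu) / ifelse(zero, 1, sdv)
  z[zero, ] <- 0
  attr(z, "zero_variance") <- stats::setNames(zero, rownames(expr))
  z
}

#' Two-group ANOVA screen for differential expression
#'
#' Per-gene one-way F statistic between the cancer and normal groups
#' (equivalent to the square of the pooled two-sample t statistic),
#' p-value from F(1, n1 + n2 - 2), Bonferroni-adjusted across genes.
#' Computed on raw values: z-scoring first would force F toward its null.
#'
#' Degenerate genes (zero within-group variance) get p = 1 when the group
#' means agree and p = 0, flagged, when they differ.
#'
#' @param cancer,normal genes x samples matrices sharing a gene namespace.
#' @param alpha Significance level applied to the adjusted p (default 0.01).
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return data.frame `gene`, `f`, `p_value`, `p_adjusted`, `selected`,
#'   `degenerate`, with attributes `alpha` and `adjust`.
#' @export
anova_screen <- function(cancer, normal, alpha = 0.01,
                         adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  n1 <- ncol(cancer)
  n2 <- ncol(normal)
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 samples")
  genes <- intersect(rownames(cancer), rownames(normal))
  if (length(genes) == 0L) stop("the two matrices share no genes")
  x1 <- cancer[genes, , drop = FALSE]
  x2 <- normal[genes, , drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  grand <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  ssw <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  df2 <- n1 + n2 - 2L
  f <- (ssb / 1) / (ssw / df2)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  degenerate <- ssw == 0
  p[degenerate & ssb == 0] <- 1
  f[degenerate & ssb == 0] <- 0
  p[degenerate & ssb > 0] <- 0
  f[degenerate & ssb > 0] <- Inf
  p_adj <- if (adjust == "bonferroni") {
    stats::p.adjust(p, method = "bonferroni")
  } else {
    p
  }
  out <- data.frame(gene = genes, f = f, p_value = p, p_adjusted = p_adj,
                    selected = p_adj < alpha,
                    degenerate = degenerate & ssb > 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  out
}

#' Assemble the protein pool from the screen and the PPI list
#'
#' The pool consists of (i) screened differential proteins that have at
#' least one PPI partner measured in the expression data, and (ii) the
#' measured one-hop PPI neighbors of those proteins ("closely associated").
#' Differential proteins with no usable interaction are eliminated; PPI
#' neighbors absent from the expression data are excluded.
#'
#' @param screen Output of [anova_screen()] (or any data.frame with `gene`
#'   and `selected`).
#' @param ppi Undirected edge table (columns `protein_a`, `protein_b`).
#' @param measured Character vector of proteins with expression data;
#'   defaults to `screen$gene`.
#' @return data.frame `protein`, `inclusion_reason`
#'   (`differential` / `neighbor_of_differential`), sorted by protein.
#' @export
build_pool <- function(screen, ppi, measured = screen$gene) {
  differential <- screen$gene[screen$selected]
  if (length(differential) == 0L) {
    warning("no differential proteins; pool is empty")
    return(data.frame(protein = character(), inclusion_reason = character(),
                      stringsAsFactors = FALSE))
  }
  a <- as.character(ppi[[1]])
  b <- as.character(ppi[[2]])
  # partners of each differential protein that are measured
  touch_a <- a %in% differential & b %in% measured
  touch_b <- b %in% differential & a %in% measured
  kept_diff <- sort(unique(c(a[touch_a], b[touch_b])))
  neighbors <- sort(unique(c(b[touch_a], a[touch_b])))
  neighbors <- setdiff(neighbors, kept_diff)
  out <- rbind(
    data.frame(protein = kept_diff,
               inclusion_reason = rep("differential", length(kept_diff)),
               stringsAsFactors = FALSE),
    data.frame(protein = neighbors,
               inclusion_reason = rep("neighbor_of_differential",
                                      length(neighbors)),
               stringsAsFactors = FALSE)
  )
  out <- out[order(out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}
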