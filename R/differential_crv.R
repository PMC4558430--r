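# Differential network, carcinogenesis relevance values (CRV),
# degree-preserving permutation p-values, and marker classification.

#' Differential interaction network
#'
#' Entrywise difference `D = A_cancer - A_normal` of two refined interaction
#' matrices over the same pool.
#'
#' @param A_cancer,A_normal Symmetric matrices with identical dimnames.
#' @return Symmetric matrix `D` with attribute `stage` copied from
#'   `A_cancer`'s `condition` attribute.
#' @export
differential_network <- function(A_cancer, A_normal) {
  if (!identical(dim(A_cancer), dim(A_normal)) ||
      !identical(rownames(A_cancer), rownames(A_normal))) {
    only_c <- setdiff(rownames(A_cancer), rownames(A_normal))
    only_n <- setdiff(rownames(A_normal), rownames(A_cancer))
    stop("matrices cover different pools; only in cancer: {",
         paste(only_c, collapse = ", "), "}; only in normal: {",
         paste(only_n, collapse = ", "), "}")
  }
  D <- unclass(A_cancer) - unclass(A_normal)
  attributes(D) <- list(dim = dim(A_cancer),
                        dimnames = dimnames(A_cancer),
                        stage = attr(A_cancer, "condition"))
  D
}

#' Carcinogenesis relevance values
#'
#' Per-protein absolute row sum of the differential matrix,
#' `CRV_i = sum_j |d_ij|` - the total change in association ability of
#' protein i between the cancer and normal networks.
#'
#' @param D Differential matrix from [differential_network()].
#' @return Named nonnegative numeric vector.
#' @export
compute_crv <- function(D) {
  rowSums(abs(D))
}

# One degree-preserving rewiring of an undirected graph via double-edge
# swaps (10 x edge count attempted swaps).
rewire_preserving_degrees <- function(graph, niter = 10L * igraph::ecount(graph)) {
  igraph::rewire(graph, igraph::keeping_degseq(niter = niter))
}

#' Empirical CRV p-values under a degree-preserving permutation null
#'
#' For each replicate the candidate network is rewired by double-edge swaps
#' (every node keeps its number of interactions) and the observed multiset
#' of absolute differential weights is randomly reassigned to the rewired
#' edges: if there are more edges than weights the surplus edges get 0; if
#' more weights than edges, a uniform subset of weights is used. Permuted
#' CRVs are computed per node and
#' `p_i = (1 + #[permuted CRV_i >= observed CRV_i]) / (n_perm + 1)`
#' (add-one smoothing, so p is never 0); `raw_fraction = TRUE` gives the
#' plain fraction instead.
#'
#' Graphs with fewer than two edges cannot be rewired; the weights are then
#' permuted over the fixed edge set, with a notice.
#'
#' @param candidate Candidate network (`igraph`) whose vertices cover `D`.
#' @param D Differential matrix over the candidate's vertices.
#' @param n_perm Number of permutation replicates (>= 1).
#' @param seed RNG seed.
#' @param raw_fraction Use the unsmoothed fraction (can be 0).
#' @return Named p-value vector over the candidate's vertices.
#' @export
permutation_pvalues <- function(candidate, D, n_perm = 1e5, seed = NULL,
                                raw_fraction = FALSE) {
  stopifnot(n_perm >= 1)
  nodes <- igraph::V(candidate)$name
  miss <- setdiff(nodes, rownames(D))
  if (length(miss)) {
    stop("differential matrix lacks candidate node(s): ",
         paste(miss, collapse = ", "))
  }
  Dn <- D[nodes, nodes, drop = FALSE]
  obs <- rowSums(abs(Dn))
  m <- igraph::ecount(candidate)
  w_obs <- abs(Dn[upper.tri(Dn)])
  w_obs <- w_obs[w_obs > 0]
  k <- length(w_obs)
  n_nodes <- length(nodes)
  rewirable <- m >= 2L
  if (!rewirable) {
    message("candidate network has ", m, " edge(s); degree-preserving ",
            "rewiring impossible - permuting weights over the fixed edge set")
  }
  counts <- integer(n_nodes)
  fixed_el <- igraph::as_edgelist(candidate, names = FALSE)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      el <- if (rewirable) {
        igraph::as_edgelist(rewire_preserving_degrees(candidate),
                            names = FALSE)
      } else {
        fixed_el
      }
      w <- if (k >= m) {
        w_obs[sample.int(k, m)]
      } else {
        padded <- c(w_obs, numeric(m - k))
        padded[sample.int(m)]
      }
      crv_b <- numeric(n_nodes)
      if (m > 0L) {
        acc <- rowsum(c(w, w), c(el[, 1], el[, 2]))
        crv_b[as.integer(rownames(acc))] <- acc[, 1]
      }
      counts <- counts + (crv_b >= obs)
    }
  })
  p <- if (raw_fraction) counts / n_perm else (1 + counts) / (n_perm + 1)
  stats::setNames(p, nodes)
}

#' Select significant proteins
#'
#' @param p Named p-value vector.
#' @param alpha Significance threshold; boundary inclusive (`p <= alpha`).
#' @return Sorted character vector of significant proteins.
#' @export
select_significant <- function(p, alpha = 0.01) {
  sort(names(p)[p <= alpha])
}

#' Classify core and stage-specific network markers
#'
#' Core markers are the significant proteins shared by both stages; each
#' stage's remaining significant proteins are its specific markers. Each
#' stage marker carries the candidate-network edges induced on its
#' significant set.
#'
#' @param sig_early,sig_late Character vectors of significant proteins.
#' @param edges Optional undirected edge table used to induce marker edges.
#' @return List of class `network_markers`: `core` (character),
#'   and per stage a list with `proteins`, `class` (named vector,
#'   `core`/`specific`) and `edges`.
#' @export
classify_markers <- function(sig_early, sig_late, edges = NULL) {
  core <- sort(intersect(sig_early, sig_late))
  stage_marker <- function(sig, stage) {
    sig <- sort(unique(sig))
    cls <- stats::setNames(ifelse(sig %in% core, "core", "specific"), sig)
    ind <- if (!is.null(edges) && nrow(edges)) {
      keep <- edges[[1]] %in% sig & edges[[2]] %in% sig
      edges[keep, 1:2, drop = FALSE]
    } else {
      data.frame(protein_a = character(), protein_b = character(),
                 stringsAsFactors = FALSE)
    }
    rownames(ind) <- NULL
    list(stage = stage, proteins = sig, class = cls, edges = ind)
  }
  out <- list(core = core,
              early = stage_marker(sig_early, "early"),
              late = stage_marker(sig_late, "late"))
  class(out) <- "network_markers"
  out
}

#' @export
print.network_markers <- function(x, ...) {
  cat("Network markers: core", length(x$core),
      "| early-specific", sum(x$early$class == "specific"),
      "| late-specific", sum(x$late$class == "specific"), "\n")
  invisible(x)
}
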