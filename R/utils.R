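# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive `n` reproducible sub-seeds (< 2^31) from one master seed, so that
# independent pipeline stages consume independent, restartable streams.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Canonicalize an undirected edge table: lexicographic pair order,
# self-loops removed, duplicates collapsed, rows sorted for byte-stable output.
canonical_edges <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  keep <- !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b) & a != b
  n_loops <- sum(a[!is.na(a) & !is.na(b)] == b[!is.na(a) & !is.na(b)])
  lo <- pmin(a[keep], b[keep])
  hi <- pmax(a[keep], b[keep])
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  out <- data.frame(protein_a = lo[!dup], protein_b = hi[!dup],
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_self_loops") <- n_loops
  out
}

# Spectral radius of a square matrix (largest eigenvalue modulus).
spectral_radius <- function(A) {
  if (nrow(A) == 0L) return(0)
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Convert a symmetric interaction matrix to an undirected edge table
#'
#' Only the upper triangle is scanned, so each unordered pair appears once.
#' Zero entries (absent interactions) are dropped.
#'
#' @param A Symmetric numeric matrix with dimnames.
#' @param value_name Column name for the edge weight.
#' @return A data.frame with columns `protein_a`, `protein_b` and the weight.
#' @export
matrix_to_edges <- function(A, value_name = "weight") {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), !is.null(rownames(A)))
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  out <- data.frame(protein_a = rownames(A)[idx[, 1]],
                    protein_b = colnames(A)[idx[, 2]],
                    value = A[idx],
                    stringsAsFactors = FALSE)
  # canonical pair order + row order for byte-stable files
  swap <- out$protein_a > out$protein_b
  tmp <- out$protein_a[swap]
  out$protein_a[swap] <- out$protein_b[swap]
  out$protein_b[swap] <- tmp
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  names(out)[3] <- value_name
  rownames(out) <- NULL
  out
}

#' Build a symmetric matrix from an undirected weighted edge table
#'
#' @param edges data.frame whose first two columns name the endpoints; the
#'   column `value_name` (default: third column) carries the weight.
#' @param proteins Character vector fixing the row/column order.
#' @param value_name Optional weight column name.
#' @return Symmetric matrix with zero diagonal over `proteins`.
#' @export
edges_to_matrix <- function(edges, proteins, value_name = NULL) {
  A <- matrix(0, length(proteins), length(proteins),
              dimnames = list(proteins, proteins))
  if (nrow(edges)) {
    w <- if (is.null(value_name)) edges[[3]] else edges[[value_name]]
    ia <- match(as.character(edges[[1]]), proteins)
    ib <- match(as.character(edges[[2]]), proteins)
    if (anyNA(ia) || anyNA(ib)) {
      stop("edge endpoints absent from `proteins`: ",
           paste(unique(c(edges[[1]][is.na(ia)], edges[[2]][is.na(ib)])),
                 collapse = ", "))
    }
    A[cbind(ia, ib)] <- w
    A[cbind(ib, ia)] <- w
  }
  A
}

# Undirected igraph from a two-column edge table, keeping isolated vertices.
edges_to_graph <- function(edges, vertices) {
  igraph::graph_from_data_frame(edges[, 1:2, drop = FALSE], directed = FALSE,
                                vertices = data.frame(name = vertices))
}
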