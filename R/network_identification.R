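# Candidate-network construction and regression-based identification of
# condition-specific interaction matrices: per-protein least-squares fits
# (the Gaussian MLE of the linear association model), AIC model-order
# selection over correlation-ranked nested models, t-test pruning of the
# surviving coefficients, and symmetric assembly of the refined matrix.

#' Build the candidate network on the protein pool
#'
#' Induced subgraph of the PPI edge list on the pool. Pool proteins without
#' any pool-internal edge remain as isolated vertices (their association
#' model is empty).
#'
#' @param pool Character vector of pool proteins (or the data.frame from
#'   [build_pool()]).
#' @param ppi Undirected edge table (first two columns are endpoints).
#' @return An undirected `igraph` graph whose vertices are the pool.
#' @export
build_candidate_network <- function(pool, ppi) {
  if (is.data.frame(pool)) pool <- pool$protein
  pool <- sort(unique(as.character(pool)))
  a <- as.character(ppi[[1]])
  b <- as.character(ppi[[2]])
  keep <- a %in% pool & b %in% pool & a != b
  edges <- canonical_edges(a[keep], b[keep])
  edges_to_graph(edges, pool)
}

# Least-squares core: no intercept (z-scored data). Returns the coefficient
# vector, residual sum of squares and a rank-deficiency flag. Rank-deficient
# designs get the minimum-norm solution via the SVD pseudoinverse.
ls_solve <- function(X, y) {
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    sv <- svd(X)
    tol <- max(dim(X)) * .Machine$double.eps * max(sv$d)
    pos <- sv$d > tol
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
    beta <- drop(beta)
    degenerate <- TRUE
  } else {
    beta <- drop(solve(qr.R(qx), t(qr.Q(qx)) %*% y))
    degenerate <- FALSE
  }
  res <- y - drop(X %*% beta)
  list(beta = beta, rss = sum(res^2), rank = qx$rank, degenerate = degenerate)
}

#' Fit the association model of one target protein
#'
#' Solves the no-intercept least-squares problem `x_i ~ sum_j alpha_ij x_j`
#' on z-scored data for one condition - the maximum-likelihood estimate of
#' the linear association model under Gaussian noise. Reports the MLE
#' residual variance (RSS/n) and per-coefficient t statistics with
#' `n - p` degrees of freedom.
#'
#' When the target has at least `n - 2` candidate interactors, the
#' predictors are pre-truncated to the `n - 2` with largest absolute
#' marginal correlation, keeping the fit well-posed on small sample groups.
#'
#' @param target Target protein id.
#' @param neighbors Character vector of candidate interactors.
#' @param Z z-scored genes x samples matrix for one condition.
#' @return Object of class `association_model`: `target`, `interactors`,
#'   `coefficients` (named), `rss`, `sigma2` (MLE), `df`, `t`, `p_value`,
#'   `n`, `degenerate`, `truncated`.
#' @export
fit_mle <- function(target, neighbors, Z) {
  if (!target %in% rownames(Z)) stop("target '", target, "' not in Z")
  neighbors <- setdiff(unique(as.character(neighbors)), target)
  miss <- setdiff(neighbors, rownames(Z))
  if (length(miss)) stop("interactor(s) not in Z: ", paste(miss, collapse = ", "))
  n <- ncol(Z)
  y <- Z[target, ]
  truncated <- FALSE
  if (length(neighbors) > n - 2L) {
    r <- abs(marginal_correlations(y, Z[neighbors, , drop = FALSE]))
    keep <- order(r, decreasing = TRUE)[seq_len(max(0L, n - 2L))]
    neighbors <- neighbors[sort(keep)]
    truncated <- TRUE
  }
  model <- list(target = target, interactors = neighbors,
                coefficients = stats::setNames(numeric(0), character(0)),
                rss = sum(y^2), sigma2 = sum(y^2) / n,
                df = n, t = numeric(0), p_value = numeric(0),
                n = n, degenerate = FALSE, truncated = truncated)
  class(model) <- "association_model"
  if (length(neighbors) == 0L) return(model)
  X <- t(Z[neighbors, , drop = FALSE])
  fit <- ls_solve(X, y)
  p <- length(neighbors)
  df <- n - fit$rank
  se <- rep(NA_real_, p)
  if (!fit$degenerate && df > 0L && fit$rss >= 0) {
    xtx_inv <- chol2inv(qr.R(qr(X)))
    se <- sqrt(pmax(fit$rss / df, 0) * diag(xtx_inv))
  }
  tval <- fit$beta / se
  model$interactors <- neighbors
  model$coefficients <- stats::setNames(fit$beta, neighbors)
  model$rss <- fit$rss
  model$sigma2 <- fit$rss / n
  model$df <- df
  model$t <- stats::setNames(tval, neighbors)
  model$p_value <- stats::setNames(2 * stats::pt(abs(tval), df,
                                                 lower.tail = FALSE),
                                   neighbors)
  model$degenerate <- fit$degenerate
  model
}

marginal_correlations <- function(y, Xrows) {
  r <- suppressWarnings(apply(Xrows, 1, stats::cor, y = y))
  r[is.na(r)] <- 0
  r
}

#' @export
print.association_model <- function(x, ...) {
  cat("Association model for", x$target, "-", length(x$coefficients),
      "interactor(s), sigma2 =", format(x$sigma2, digits = 4), "\n")
  invisible(x)
}

#' Prune an association model by AIC order selection and t-tests
#'
#' Candidate interactors are ranked by decreasing absolute marginal
#' correlation with the target; nested models of order m = 0..M are fitted
#' and the Gaussian profile-likelihood AIC, `n log(RSS_m / n) + 2m`, picks
#' the order. The surviving coefficients are re-fitted jointly and each
#' tested two-sided against zero; coefficients with p >= `t_alpha` are
#' removed and the model re-fitted once more. The remaining interactor set
#' is final, possibly empty.
#'
#' @param model An `association_model` from [fit_mle()].
#' @param Z The z-scored matrix the model was fitted on.
#' @param t_alpha Two-sided coefficient-test threshold (default 0.05).
#' @return The pruned `association_model`, with attribute fields
#'   `order_selected` (AIC order) and `aic` (the AIC path).
#' @export
prune_aic <- function(model, Z, t_alpha = 0.05) {
  stopifnot(inherits(model, "association_model"))
  nb <- model$interactors
  if (length(nb) == 0L) {
    model$order_selected <- 0L
    return(model)
  }
  n <- ncol(Z)
  y <- Z[model$target, ]
  r <- abs(marginal_correlations(y, Z[nb, , drop = FALSE]))
  ranked <- nb[order(r, decreasing = TRUE)]
  rss_path <- numeric(length(nb) + 1L)
  rss_path[1] <- sum(y^2)
  for (m in seq_along(ranked)) {
    X <- t(Z[ranked[seq_len(m)], , drop = FALSE])
    rss_path[m + 1L] <- ls_solve(X, y)$rss
  }
  aic <- n * log(pmax(rss_path, 0) / n) + 2 * (0:length(ranked))
  aic[rss_path <= 0] <- -Inf
  m_star <- which.min(aic) - 1L
  selected <- ranked[seq_len(m_star)]
  refit <- function(keep) {
    if (length(keep) == 0L) {
      out <- fit_mle(model$target, character(0), Z)
    } else {
      out <- fit_mle(model$target, keep, Z)
    }
    out
  }
  out <- refit(selected)
  drop_p <- names(out$p_value)[!is.na(out$p_value) & out$p_value >= t_alpha |
                                 is.na(out$p_value)]
  # keep exact fits: p is NaN when rss = 0 (perfect reconstruction)
  exact <- out$rss <= .Machine$double.eps * max(1, sum(y^2))
  if (exact) drop_p <- character(0)
  if (length(drop_p)) {
    out <- refit(setdiff(out$interactors, drop_p))
  }
  out$order_selected <- m_star
  out$aic <- aic
  out
}

#' Assemble a symmetric interaction matrix from per-protein models
#'
#' Each unordered pair may carry up to two directed estimates (from the two
#' endpoint models); the one with the larger absolute value is used for both
#' entries. Pairs pruned in both directions are absent (zero). The diagonal
#' is zero.
#'
#' @param models List of `association_model` objects covering the pool.
#' @param pool Character vector fixing the matrix order.
#' @param condition Condition label stored in the `condition` attribute.
#' @return Symmetric numeric matrix over `pool`.
#' @export
assemble_matrix <- function(models, pool, condition = NA_character_) {
  pool <- as.character(pool)
  A <- matrix(0, length(pool), length(pool), dimnames = list(pool, pool))
  for (model in models) {
    i <- model$target
    for (j in names(model$coefficients)) {
      v <- model$coefficients[[j]]
      if (abs(v) > abs(A[i, j])) {
        A[i, j] <- v
        A[j, i] <- v
      }
    }
  }
  attr(A, "condition") <- condition
  A
}

#' Identify the refined interaction matrix for one condition
#'
#' Runs [fit_mle()] + [prune_aic()] for every pool protein against its
#' candidate-network neighbors and assembles the symmetric refined matrix.
#'
#' @param Z z-scored genes x samples matrix (one condition).
#' @param candidate Candidate network from [build_candidate_network()].
#' @param t_alpha Coefficient-test threshold passed to [prune_aic()].
#' @param condition Condition label.
#' @return Symmetric interaction matrix over the candidate's vertices.
#' @export
identify_network <- function(Z, candidate, t_alpha = 0.05,
                             condition = NA_character_) {
  pool <- igraph::V(candidate)$name
  miss <- setdiff(pool, rownames(Z))
  if (length(miss)) {
    stop("pool protein(s) without expression: ", paste(miss, collapse = ", "))
  }
  models <- lapply(pool, function(i) {
    nb <- igraph::neighbors(candidate, i)$name
    if (length(nb) == 0L) return(NULL)
    prune_aic(fit_mle(i, nb, Z), Z, t_alpha = t_alpha)
  })
  assemble_matrix(Filter(Negate(is.null), models), pool, condition)
}
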