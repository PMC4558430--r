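# Candidate networks, per-protein MLE fits, AIC order selection with t-test
# pruning, and symmetric matrix assembly.

test_that("candidate network is the induced subgraph on the pool", {
  ppi <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "D"))
  g <- build_candidate_network(c("A", "B", "C"), ppi)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 1)
  expect_true(igraph::are_adjacent(g, "A", "B"))
  full <- data.frame(protein_a = c("A", "A", "A", "B", "B", "C"),
                     protein_b = c("B", "C", "D", "C", "D", "D"))
  g4 <- build_candidate_network(c("A", "B", "C", "D"), full)
  expect_identical(unname(igraph::degree(g4)), rep(3, 4))
  g0 <- build_candidate_network(character(0), ppi)
  expect_equal(igraph::vcount(g0), 0)
})

test_that("a perfectly predictive neighbor is fitted exactly", {
  x <- c(-1.2, 0.3, 0.8, -0.5, 0.6)
  Z <- rbind(t = x, j = x)
  colnames(Z) <- paste0("s", 1:5)
  m <- fit_mle("t", "j", Z)
  expect_equal(unname(m$coefficients["j"]), 1, tolerance = 1e-12)
  expect_equal(m$sigma2, 0, tolerance = 1e-12)
})

test_that("MLE coefficients equal the closed-form normal-equations solution", {
  set.seed(11)
  for (i in 1:20) {
    n <- 50L
    p <- 5L
    Z <- matrix(stats::rnorm((p + 1) * n), p + 1, n,
                dimnames = list(c("y", paste0("x", 1:p)), paste0("s", 1:n)))
    m <- fit_mle("y", paste0("x", 1:p), Z)
    X <- t(Z[-1, , drop = FALSE])
    y <- Z[1, ]
    beta_oracle <- solve(t(X) %*% X, t(X) %*% y)[, 1]
    expect_equal(unname(m$coefficients), unname(beta_oracle),
                 tolerance = 1e-10)
    # and the lm cross-check, including t statistics
    lmfit <- summary(stats::lm(y ~ 0 + X))
    expect_equal(unname(m$t), unname(lmfit$coefficients[, "t value"]),
                 tolerance = 1e-8)
  }
})

test_that("an uncorrelated neighbor's coefficient concentrates at zero", {
  set.seed(21)
  n <- 10000L
  Z <- matrix(stats::rnorm(2 * n), 2, n,
              dimnames = list(c("t", "j"), paste0("s", 1:n)))
  m <- fit_mle("t", "j", Z)
  expect_lt(abs(unname(m$coefficients["j"])), 3 / sqrt(n))
})

test_that("the predictor guard truncates wide designs by marginal correlation", {
  set.seed(31)
  n <- 8L
  Z <- matrix(stats::rnorm(12 * n), 12, n,
              dimnames = list(c("y", paste0("x", 1:11)), paste0("s", 1:n)))
  m <- fit_mle("y", paste0("x", 1:11), Z)
  expect_true(m$truncated)
  expect_lte(length(m$coefficients), n - 2L)
})

test_that("AIC keeps the informative neighbor and prunes the noise one", {
  set.seed(41)
  n <- 40L
  xj <- stats::rnorm(n)
  noise <- stats::rnorm(n)
  Z <- rbind(t = 0.7 * xj, j = xj, k = noise)
  colnames(Z) <- paste0("s", 1:n)
  m <- prune_aic(fit_mle("t", c("j", "k"), Z), Z)
  expect_identical(names(m$coefficients), "j")
  expect_identical(m$order_selected, 1L)
  expect_equal(unname(m$coefficients["j"]), 0.7, tolerance = 1e-10)
})

test_that("forward AIC equals exhaustive best-subset AIC on orthogonal designs", {
  set.seed(51)
  n <- 32L
  p <- 5L
  for (rep in 1:5) {
    # mean-zero orthonormal columns, so |marginal correlation| ranking and
    # projection magnitude agree exactly
    Q <- qr.Q(qr(scale(matrix(stats::rnorm(n * p), n, p), scale = FALSE)))
    true_set <- sort(sample(p, sample(0:p, 1)))
    beta <- numeric(p)
    beta[true_set] <- stats::runif(length(true_set), 0.5, 1)
    y <- drop(Q %*% beta) + stats::rnorm(n, sd = 0.3)
    Z <- rbind(y = y, t(Q))
    rownames(Z) <- c("y", paste0("x", 1:p))
    colnames(Z) <- paste0("s", 1:n)
    model <- fit_mle("y", paste0("x", 1:p), Z)
    pruned <- prune_aic(model, Z, t_alpha = 1)  # isolate the AIC stage
    # exhaustive oracle over all 2^p subsets
    best_aic <- Inf
    best_set <- integer(0)
    for (mask in 0:(2^p - 1)) {
      s <- which(bitwAnd(mask, 2^(0:(p - 1))) > 0)
      rss <- sum((y - if (length(s)) Q[, s, drop = FALSE] %*%
                    crossprod(Q[, s, drop = FALSE], y) else 0)^2)
      aic <- n * log(rss / n) + 2 * length(s)
      if (aic < best_aic) {
        best_aic <- aic
        best_set <- s
      }
    }
    expect_setequal(names(pruned$coefficients), paste0("x", sort(best_set)))
  }
})

test_that("null neighbors are falsely retained at most at the t-test level", {
  set.seed(61)
  reps <- 1000L
  n <- 40L
  retained <- vapply(seq_len(reps), function(i) {
    Z <- matrix(stats::rnorm(4 * n), 4, n,
                dimnames = list(c("y", "a", "b", "c"), paste0("s", 1:n)))
    m <- prune_aic(fit_mle("y", c("a", "b", "c"), Z), Z)
    length(m$coefficients) / 3
  }, numeric(1))
  rate <- mean(retained)
  se <- sqrt(0.05 * 0.95 / (3 * reps))
  expect_lte(rate, 0.05 + 2 * se)
})

test_that("pure-noise candidate edges never perturb an exact model", {
  set.seed(71)
  n <- 30L
  xj <- stats::rnorm(n)
  Z <- rbind(t = 0.5 * xj, j = xj,
             matrix(stats::rnorm(3 * n), 3, n))
  rownames(Z) <- c("t", "j", "n1", "n2", "n3")
  colnames(Z) <- paste0("s", 1:n)
  clean <- prune_aic(fit_mle("t", "j", Z), Z)
  noisy <- prune_aic(fit_mle("t", c("j", "n1", "n2", "n3"), Z), Z)
  expect_identical(names(noisy$coefficients), "j")
  expect_equal(noisy$coefficients["j"], clean$coefficients["j"],
               tolerance = 1e-12)
})

test_that("matrix assembly takes the larger-magnitude directed estimate", {
  mk <- function(target, coefs) {
    structure(list(target = target, coefficients = coefs),
              class = "association_model")
  }
  pool <- c("A", "B", "C")
  models <- list(mk("A", c(B = 0.4)), mk("B", c(A = -0.6, C = 0.3)))
  A <- assemble_matrix(models, pool, "test")
  expect_equal(A["A", "B"], -0.6)
  expect_equal(A["B", "A"], -0.6)
  expect_equal(A["B", "C"], 0.3)   # single-sided survival
  expect_equal(A["C", "B"], 0.3)
  expect_equal(A["A", "C"], 0)     # pruned in both directions
  expect_identical(unname(A), unname(t(A)))
  expect_true(all(diag(A) == 0))
})

test_that("identified matrices are symmetric with support inside the candidates", {
  ds <- generate_dataset(tiny_config(n_early = 60L))
  g <- build_candidate_network(rownames(ds$expression$early),
                               ds$candidate_edges)
  A <- identify_network(z_transform(ds$expression$early), g,
                        condition = "cancer-early")
  expect_identical(unname(A), unname(t(A)))
  expect_true(all(diag(A) == 0))
  allowed <- edges_to_matrix(cbind(ds$candidate_edges, w = 1),
                             rownames(A), "w")
  expect_true(all(A[allowed == 0] == 0))
})
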