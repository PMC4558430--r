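# Synthetic-data generator: ground-truth interaction networks, expression
# samples from the linear association model, and a contaminated candidate
# edge list, so the whole pipeline is testable without external data.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. The defaults mirror a
#' liver-cancer RNA-seq study design: 19 early-stage and 18 late-stage tumor
#' samples against 24 adjacent-normal samples, a sparse interaction network
#' of mean degree 3, and association strengths drawn from \[0.3, 0.8\] with
#' random sign.
#'
#' @param n_proteins Number of proteins (network nodes).
#' @param n_early,n_late,n_normal Sample counts per condition.
#' @param mean_degree Target mean degree of the true interaction graph.
#' @param alpha_range Interval of absolute association weights.
#' @param differential_edge_fraction Fraction of true edges whose weight is
#'   perturbed in each cancer matrix relative to normal.
#' @param false_positive_edge_fraction Fraction of the candidate edge list
#'   made up of edges absent from every true network.
#' @param noise_sd Standard deviation of the stochastic noise term of the
#'   association model.
#' @param spectral_cap Upper bound (< 1) on the spectral radius of each true
#'   interaction matrix; guarantees the simultaneous system has a stationary
#'   solution.
#' @param differential_mode `"redraw"` re-draws perturbed weights from
#'   `alpha_range` with random sign; `"delete"` zeroes them (edge loss).
#' @param graph_model `"gnm"` for an Erdos-Renyi graph with fixed edge count,
#'   `"degseq"` for a configuration-model graph with `degree_sequence`.
#' @param degree_sequence Integer degree sequence, required for
#'   `graph_model = "degseq"`.
#' @param mean_shift Raw-scale expression offset added to connected proteins
#'   in the cancer samples, so the differential-expression screen has signal
#'   (the association model itself is mean-free).
#' @param rpkm_scale Multiplier mapping latent z-like values to the
#'   RPKM-like output scale.
#' @param seed Master RNG seed; every generator stage derives its own
#'   sub-seed from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 50L,
                              n_early = 19L,
                              n_late = 18L,
                              n_normal = 24L,
                              mean_degree = 3,
                              alpha_range = c(0.3, 0.8),
                              differential_edge_fraction = 0.2,
                              false_positive_edge_fraction = 0.2,
                              noise_sd = 0.5,
                              spectral_cap = 0.9,
                              differential_mode = c("redraw", "delete"),
                              graph_model = c("gnm", "degseq"),
                              degree_sequence = NULL,
                              mean_shift = 100,
                              rpkm_scale = 100,
                              seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    n_early = as.integer(n_early),
    n_late = as.integer(n_late),
    n_normal = as.integer(n_normal),
    mean_degree = mean_degree,
    alpha_range = sort(as.numeric(alpha_range)),
    differential_edge_fraction = differential_edge_fraction,
    false_positive_edge_fraction = false_positive_edge_fraction,
    noise_sd = noise_sd,
    spectral_cap = spectral_cap,
    differential_mode = match.arg(differential_mode),
    graph_model = match.arg(graph_model),
    degree_sequence = degree_sequence,
    mean_shift = mean_shift,
    rpkm_scale = rpkm_scale,
    seed = as.integer(seed)
  )
  counts <- c(cfg$n_proteins, cfg$n_early, cfg$n_late, cfg$n_normal)
  if (any(counts <= 0L)) stop("all counts must be > 0")
  if (cfg$mean_degree <= 0) stop("mean_degree must be positive")
  if (cfg$mean_degree >= cfg$n_proteins) {
    stop("mean_degree (", cfg$mean_degree,
         ") must be smaller than n_proteins (", cfg$n_proteins, ")")
  }
  for (f in c("differential_edge_fraction", "false_positive_edge_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$false_positive_edge_fraction >= 1) {
    # handled again at generation time; fraction 1 is never valid
    stop("false_positive_edge_fraction must be < 1")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$spectral_cap <= 0 || cfg$spectral_cap >= 1) {
    stop("spectral_cap must lie strictly between 0 and 1")
  }
  if (length(cfg$alpha_range) != 2L || any(cfg$alpha_range < 0)) {
    stop("alpha_range must be a nonnegative interval")
  }
  if (cfg$graph_model == "degseq" && is.null(cfg$degree_sequence)) {
    stop("graph_model = 'degseq' requires a degree_sequence")
  }
  class(cfg) <- "simulation_config"
  cfg
}

protein_names <- function(n) sprintf("P%03d", seq_len(n))

draw_weights <- function(n, alpha_range) {
  stats::runif(n, alpha_range[1], alpha_range[2]) *
    sample(c(-1, 1), n, replace = TRUE)
}

#' Generate the three ground-truth interaction matrices
#'
#' Draws one undirected support graph, assigns symmetric weights, then
#' perturbs an independent subset of edges in each cancer matrix (weight
#' re-draw or deletion). All three matrices are rescaled by one common
#' factor so every spectral radius is at most `spectral_cap`; a common
#' factor keeps unperturbed entries identical across conditions.
#'
#' @param config A [simulation_config()].
#' @return List with symmetric matrices `normal`, `early`, `late`
#'   (zero diagonal, shared dimnames).
#' @export
generate_true_networks <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_proteins
  prot <- protein_names(n)
  seeds <- derive_seeds(config$seed, 4L)
  g <- with_seed(seeds[1], {
    if (config$graph_model == "gnm") {
      m <- max(1L, round(n * config$mean_degree / 2))
      igraph::sample_gnm(n, m)
    } else {
      igraph::sample_degseq(config$degree_sequence, method = "vl")
    }
  })
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  A <- matrix(0, n, n, dimnames = list(prot, prot))
  w <- with_seed(seeds[2], draw_weights(m, config$alpha_range))
  A[el] <- w
  A[el[, 2:1, drop = FALSE]] <- w

  perturb <- function(A0, seed) {
    n_diff <- round(config$differential_edge_fraction * m)
    if (n_diff == 0L) return(A0)
    with_seed(seed, {
      pick <- sample.int(m, n_diff)
      new_w <- if (config$differential_mode == "redraw") {
        draw_weights(n_diff, config$alpha_range)
      } else {
        numeric(n_diff)
      }
      A0[el[pick, , drop = FALSE]] <- new_w
      A0[el[pick, 2:1, drop = FALSE]] <- new_w
      A0
    })
  }
  mats <- list(normal = A,
               early = perturb(A, seeds[3]),
               late = perturb(A, seeds[4]))
  rho <- vapply(mats, spectral_radius, numeric(1))
  if (max(rho) > config$spectral_cap) {
    f <- config$spectral_cap / max(rho)
    mats <- lapply(mats, function(x) x * f)
  }
  mats
}

#' Simulate expression samples from an interaction matrix
#'
#' Each sample is drawn from the stationary Gaussian law of the
#' simultaneous association model, `x ~ N(0, noise_sd^2 (I - A)^-1)`. This
#' is the distribution whose full conditionals are exactly the per-protein
#' regression `x_i = sum_j alpha_ij x_j + omega_i` with
#' `omega_i ~ N(0, noise_sd^2)` independent of the interactors, so
#' re-fitting the model recovers `A` consistently (the naive fixed-point
#' draw `x = (I - A)^-1 w` would instead give regression coefficients near
#' `2 alpha` by simultaneity). Latent values are then mapped affinely to a
#' nonnegative RPKM-like scale (`value = (x - shift) * scale` with
#' `shift = min(x) - 0.5`); the affine parameters are recorded in
#' attributes `shift` and `scale`, and downstream analysis re-z-transforms
#' per gene, so the map carries no information.
#'
#' @param A Symmetric interaction matrix with spectral radius < 1.
#' @param n_samples Number of samples (columns).
#' @param noise_sd Noise standard deviation.
#' @param seed RNG seed.
#' @param rpkm_scale Output scale multiplier.
#' @param sample_prefix Prefix for generated sample ids.
#' @return genes x samples numeric matrix of nonnegative values.
#' @export
generate_expression <- function(A, n_samples, noise_sd = 0.5, seed = 1L,
                                rpkm_scale = 100, sample_prefix = "S") {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), n_samples >= 1, noise_sd > 0)
  rho <- spectral_radius(A)
  if (rho >= 1) {
    stop("interaction matrix has spectral radius ", format(rho),
         " >= 1; (I - A) is (near-)singular and the model has no ",
         "stationary solution")
  }
  n <- nrow(A)
  W <- with_seed(seed, matrix(stats::rnorm(n * n_samples, sd = noise_sd),
                              n, n_samples))
  # x = R^-1 w with R'R = I - A gives Cov(x) = noise_sd^2 (I - A)^-1
  R <- chol(diag(n) - A)
  X <- backsolve(R, W)
  shift <- min(X) - 0.5
  out <- (X - shift) * rpkm_scale
  dimnames(out) <- list(rownames(A),
                        sprintf("%s%03d", sample_prefix, seq_len(n_samples)))
  attr(out, "shift") <- shift
  attr(out, "scale") <- rpkm_scale
  out
}

#' Build a contaminated candidate edge list
#'
#' Takes the union of the true edge sets and adds uniformly sampled
#' non-edges ("false positives", emulating interactions reported under
#' other conditions or organisms) until they make up the requested fraction
#' of the output.
#'
#' @param networks List of true interaction matrices (shared dimnames).
#' @param false_positive_edge_fraction Fraction of output edges that are
#'   absent from every true network; must be in `[0, 1)`.
#' @param seed RNG seed.
#' @return data.frame with columns `protein_a`, `protein_b` (canonical
#'   order, no duplicates, no self-loops).
#' @export
generate_candidate_edges <- function(networks, false_positive_edge_fraction,
                                     seed = 1L) {
  if (false_positive_edge_fraction < 0 || false_positive_edge_fraction >= 1) {
    stop("false_positive_edge_fraction must lie in [0, 1); a fraction of 1 ",
         "would require infinitely many false edges")
  }
  support <- Reduce(`|`, lapply(networks, function(A) A != 0))
  prot <- rownames(networks[[1]])
  idx <- which(upper.tri(support) & support, arr.ind = TRUE)
  true_edges <- data.frame(protein_a = prot[idx[, 1]], protein_b = prot[idx[, 2]],
                           stringsAsFactors = FALSE)
  n_true <- nrow(true_edges)
  n_fp <- round(false_positive_edge_fraction /
                  (1 - false_positive_edge_fraction) * n_true)
  fp_edges <- NULL
  if (n_fp > 0L) {
    non <- which(upper.tri(support) & !support, arr.ind = TRUE)
    if (nrow(non) < n_fp) {
      stop("not enough non-edges (", nrow(non), ") to sample ", n_fp,
           " false positives")
    }
    pick <- with_seed(seed, sample.int(nrow(non), n_fp))
    fp_edges <- data.frame(protein_a = prot[non[pick, 1]],
                           protein_b = prot[non[pick, 2]],
                           stringsAsFactors = FALSE)
  }
  all_edges <- rbind(true_edges, fp_edges)
  out <- canonical_edges(all_edges$protein_a, all_edges$protein_b)
  attr(out, "n_self_loops") <- NULL
  out
}

# Proteins incident to at least one edge whose weight differs between a
# cancer matrix and the normal matrix.
differential_proteins <- function(A_cancer, A_normal) {
  diff <- A_cancer != A_normal
  sort(rownames(A_cancer)[rowSums(diff) > 0])
}

#' Generate a complete synthetic dataset
#'
#' Orchestrates [generate_true_networks()], [generate_expression()] per
#' condition and [generate_candidate_edges()], adds the cancer-group mean
#' shift to connected proteins, and derives the ground-truth differential
#' protein sets by comparing the true matrices.
#'
#' @param config A [simulation_config()].
#' @return List of class `crv_dataset` with elements `config`, `networks`,
#'   `expression` (matrices `normal`, `early`, `late`), `sample_sheet`,
#'   `candidate_edges` and `truth` (character vectors `early`, `late`).
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  nets <- generate_true_networks(config)
  seeds <- derive_seeds(config$seed + 1L, 4L)
  expr <- list(
    normal = generate_expression(nets$normal, config$n_normal,
                                 config$noise_sd, seeds[1],
                                 config$rpkm_scale, "N"),
    early = generate_expression(nets$early, config$n_early,
                                config$noise_sd, seeds[2],
                                config$rpkm_scale, "E"),
    late = generate_expression(nets$late, config$n_late,
                               config$noise_sd, seeds[3],
                               config$rpkm_scale, "L")
  )
  # raw-scale dysregulation of the interacting module in tumors, so the
  # differential-expression screen can find the pool
  connected <- rowSums(nets$normal != 0 | nets$early != 0 | nets$late != 0) > 0
  expr$early[connected, ] <- expr$early[connected, ] + config$mean_shift
  expr$late[connected, ] <- expr$late[connected, ] + config$mean_shift
  sheet <- data.frame(
    sample_id = c(colnames(expr$early), colnames(expr$late),
                  colnames(expr$normal)),
    condition = rep(c("cancer", "cancer", "normal"),
                    c(config$n_early, config$n_late, config$n_normal)),
    stage = rep(c("early", "late", "none"),
                c(config$n_early, config$n_late, config$n_normal)),
    stringsAsFactors = FALSE
  )
  out <- list(
    config = config,
    networks = nets,
    expression = expr,
    sample_sheet = sheet,
    candidate_edges = generate_candidate_edges(
      nets, config$false_positive_edge_fraction, seeds[4]),
    truth = list(early = differential_proteins(nets$early, nets$normal),
                 late = differential_proteins(nets$late, nets$normal))
  )
  class(out) <- "crv_dataset"
  out
}

#' @export
print.crv_dataset <- function(x, ...) {
  cat("Synthetic CRV dataset:", x$config$n_proteins, "proteins;",
      sum(x$networks$normal[upper.tri(x$networks$normal)] != 0), "true edges;",
      nrow(x$candidate_edges), "candidate edges\n")
  cat("samples: early", x$config$n_early, "/ late", x$config$n_late,
      "/ normal", x$config$n_normal, "\n")
  cat("differential proteins: early", length(x$truth$early),
      "/ late", length(x$truth$late), "\n")
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `expression.tsv` (all conditions, genes x samples),
#' `sample_sheet.tsv`, `candidate_edges.tsv`, per-condition true-network
#' edge tables and `truth.tsv` (protein, stage of differential membership),
#' all readable by the package's readers.
#'
#' @param dataset A `crv_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "crv_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- do.call(cbind, unname(dataset$expression[c("early", "late", "normal")]))
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    sample_sheet = file.path(dir, "sample_sheet.tsv"),
    candidate_edges = file.path(dir, "candidate_edges.tsv"),
    truth = file.path(dir, "truth.tsv"),
    network_normal = file.path(dir, "true_network_normal.tsv"),
    network_early = file.path(dir, "true_network_early.tsv"),
    network_late = file.path(dir, "true_network_late.tsv")
  )
  write_expression(expr, paths["expression"])
  write_sample_sheet(dataset$sample_sheet, paths["sample_sheet"])
  write_tsv(dataset$candidate_edges, paths["candidate_edges"])
  truth <- rbind(
    data.frame(protein_id = dataset$truth$early,
               stage = rep("early", length(dataset$truth$early)),
               stringsAsFactors = FALSE),
    data.frame(protein_id = dataset$truth$late,
               stage = rep("late", length(dataset$truth$late)),
               stringsAsFactors = FALSE)
  )
  write_tsv(truth, paths["truth"])
  for (cond in c("normal", "early", "late")) {
    write_tsv(matrix_to_edges(dataset$networks[[cond]], "alpha"),
              paths[paste0("network_", cond)])
  }
  invisible(paths)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir Directory produced by [write_dataset()].
#' @return List with `expression`, `sample_sheet`, `candidate_edges`,
#'   `truth` and `networks` (symmetric matrices).
#' @export
read_dataset <- function(dir) {
  expr <- read_expression(file.path(dir, "expression.tsv"))
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  truth_tab <- utils::read.delim(file.path(dir, "truth.tsv"),
                                 stringsAsFactors = FALSE,
                                 colClasses = "character")
  nets <- lapply(c(normal = "normal", early = "early", late = "late"),
                 function(cond) {
    e <- utils::read.delim(file.path(dir, paste0("true_network_", cond, ".tsv")),
                           stringsAsFactors = FALSE)
    edges_to_matrix(e, rownames(expr), "alpha")
  })
  list(
    expression = expr,
    sample_sheet = sheet,
    candidate_edges = read_ppi_edges(file.path(dir, "candidate_edges.tsv"),
                                     c("protein_a", "protein_b")),
    truth = list(early = sort(truth_tab$protein_id[truth_tab$stage == "early"]),
                 late = sort(truth_tab$protein_id[truth_tab$stage == "late"])),
    networks = nets
  )
}
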