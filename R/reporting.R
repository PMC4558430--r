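# Result tables (average expressions, log2 fold changes, marker tables)
# and the end-to-end pipeline driver.

#' Per-gene average expression over a sample set
#'
#' Arithmetic mean of raw (pre-normalization) values.
#'
#' @param expr genes x samples matrix of raw values.
#' @param samples Sample ids; must all exist as columns.
#' @return Named per-gene mean vector.
#' @export
average_expression <- function(expr, samples) {
  if (length(samples) == 0L) stop("sample set is empty")
  miss <- setdiff(samples, colnames(expr))
  if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  rowMeans(expr[, samples, drop = FALSE])
}

#' Log2 fold change of two positive averages
#'
#' `log2(case / control)`; undefined (NA) when either argument is not
#' strictly positive.
#'
#' @param case_avg,control_avg Numeric vectors (recycled).
#' @return Numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(case_avg, control_avg) {
  out <- ifelse(case_avg > 0 & control_avg > 0,
                log2(case_avg / control_avg), NA_real_)
  unname(out)
}

#' Assemble a per-protein marker table
#'
#' One row per protein with its CRV, empirical p-value, raw average
#' expressions over the stage's cancer samples and the normal samples,
#' log2 fold change, and marker class. Rows are sorted by descending CRV.
#'
#' @param crv Named CRV vector.
#' @param p Named p-value vector (same names).
#' @param expr Raw genes x samples expression matrix.
#' @param cancer_samples,normal_samples Sample id vectors.
#' @param marker_class Named class vector (`core`/`specific`/...); proteins
#'   absent from it get `"none"`.
#' @return data.frame in the node-table column order.
#' @export
marker_table <- function(crv, p, expr, cancer_samples, normal_samples,
                         marker_class = NULL) {
  prot <- names(crv)
  cancer_avg <- average_expression(expr, cancer_samples)[prot]
  control_avg <- average_expression(expr, normal_samples)[prot]
  cls <- rep("none", length(prot))
  if (!is.null(marker_class)) {
    hit <- match(prot, names(marker_class))
    cls[!is.na(hit)] <- marker_class[hit[!is.na(hit)]]
  }
  out <- data.frame(
    protein = prot,
    crv = unname(crv),
    p_value = unname(p[prot]),
    cancer_avg_exp = unname(cancer_avg),
    control_avg_exp = unname(control_avg),
    log2_fc = log2_fold_change(cancer_avg, control_avg),
    marker_class = cls,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$crv, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' @param expression,sample_sheet,ppi Input file paths (TSV).
#' @param outdir Output directory.
#' @param pool_alpha Significance level of the differential-expression
#'   screen (applied to the adjusted p-value).
#' @param adjust Multiple-testing adjustment of the screen
#'   (`bonferroni`/`none`).
#' @param norm_scope `"per-group"` z-transforms each model-fitting group
#'   separately (cancer stage vs normal); `"joint"` uses one transform over
#'   all samples.
#' @param t_alpha Coefficient t-test threshold of the network
#'   identification.
#' @param crv_alpha CRV significance threshold (boundary inclusive).
#' @param n_perm Permutation replicates for the CRV null.
#' @param raw_fraction Use unsmoothed permutation p-values.
#' @param stages Cancer stages to fit (`early`, `late`, `total`).
#' @param seed Master seed for the permutation null.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, sample_sheet, ppi, outdir,
                            pool_alpha = 0.01,
                            adjust = c("bonferroni", "none"),
                            norm_scope = c("per-group", "joint"),
                            t_alpha = 0.05,
                            crv_alpha = 0.01,
                            n_perm = 1e5,
                            raw_fraction = FALSE,
                            stages = c("early", "late", "total"),
                            seed = 1L) {
  cfg <- list(expression = expression, sample_sheet = sample_sheet, ppi = ppi,
              outdir = outdir, pool_alpha = pool_alpha,
              adjust = match.arg(adjust), norm_scope = match.arg(norm_scope),
              t_alpha = t_alpha, crv_alpha = crv_alpha,
              n_perm = as.integer(n_perm), raw_fraction = raw_fraction,
              stages = match.arg(stages, several.ok = TRUE),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage_samples <- function(sheet, stage) {
  switch(stage,
         early = sheet$sample_id[sheet$stage == "early"],
         late = sheet$sample_id[sheet$stage == "late"],
         total = sheet$sample_id[sheet$condition == "cancer"],
         stop("unknown stage '", stage, "'"))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full network-marker pipeline
#'
#' Reads the inputs, screens for differential proteins (ANOVA + Bonferroni),
#' builds the pool and candidate network, identifies the refined noncancer
#' network once and a cancer network per stage, computes differential
#' matrices, CRVs and degree-preserving permutation p-values, classifies
#' core vs stage-specific markers, and writes node/edge/SIF tables plus a
#' run manifest. All computation happens before any file is written, so a
#' failing stage leaves no partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the screen, pool, candidate network,
#'   interaction matrices, per-stage results and markers.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  expr <- run_stage("read_expression", read_expression(config$expression))
  sheet <- run_stage("read_sample_sheet",
                     read_sample_sheet(config$sample_sheet, expr))
  ppi <- run_stage("read_ppi_edges", {
    e <- utils::read.delim(config$ppi, check.names = FALSE, nrows = 1)
    defaults <- c("Official Symbol Interactor A", "Official Symbol Interactor B")
    cols <- if (all(defaults %in% names(e))) defaults else names(e)[1:2]
    read_ppi_edges(config$ppi, cols)
  })
  normal_samples <- sheet$sample_id[sheet$condition == "normal"]
  cancer_samples <- sheet$sample_id[sheet$condition == "cancer"]

  screen <- run_stage("anova_screen",
                      anova_screen(expr[, cancer_samples, drop = FALSE],
                                   expr[, normal_samples, drop = FALSE],
                                   alpha = config$pool_alpha,
                                   adjust = config$adjust))
  pool <- run_stage("build_pool", build_pool(screen, ppi))
  candidate <- run_stage("build_candidate_network",
                         build_candidate_network(pool, ppi))

  z_for <- function(samples) {
    if (config$norm_scope == "joint") {
      z_transform(expr)[, samples, drop = FALSE]
    } else {
      z_transform(expr, samples)
    }
  }
  A_normal <- run_stage("identify_network_normal",
                        identify_network(z_for(normal_samples), candidate,
                                         config$t_alpha, "normal"))
  perm_seed <- derive_seeds(config$seed, 1L)

  stages <- lapply(config$stages, function(stage) {
    run_stage(paste0("stage_", stage), {
      smp <- stage_samples(sheet, stage)
      A_c <- identify_network(z_for(smp), candidate, config$t_alpha,
                              paste0("cancer-", stage))
      D <- differential_network(A_c, A_normal)
      crv <- compute_crv(D)
      # one shared sub-seed: identical stage inputs give identical outputs
      p <- permutation_pvalues(candidate, D, config$n_perm, perm_seed,
                               config$raw_fraction)
      list(stage = stage, samples = smp, A_cancer = A_c, D = D,
           crv = crv, p = p,
           significant = select_significant(p, config$crv_alpha))
    })
  })
  names(stages) <- config$stages

  cand_df <- igraph::as_data_frame(candidate, "edges")
  cand_edges <- canonical_edges(cand_df$from, cand_df$to)
  attr(cand_edges, "n_self_loops") <- NULL
  markers <- NULL
  if (all(c("early", "late") %in% names(stages))) {
    markers <- classify_markers(stages$early$significant,
                                stages$late$significant,
                                cand_edges)
  }

  # ---- write outputs ----
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(screen, file.path(config$outdir, "screen.tsv"))
  write_tsv(pool, file.path(config$outdir, "pool.tsv"))
  for (st in stages) {
    cls <- if (!is.null(markers) && st$stage %in% c("early", "late")) {
      markers[[st$stage]]$class
    } else if (length(st$significant)) {
      stats::setNames(rep(st$stage, length(st$significant)), st$significant)
    } else {
      NULL
    }
    nt <- marker_table(st$crv, st$p, expr, st$samples, normal_samples, cls)
    write_node_table(nt, file.path(config$outdir,
                                   paste0("node_table_", st$stage, ".tsv")))
    et <- data.frame(
      cand_edges[, c("protein_a", "protein_b")],
      alpha_cancer = st$A_cancer[cbind(cand_edges$protein_a,
                                       cand_edges$protein_b)],
      alpha_normal = A_normal[cbind(cand_edges$protein_a,
                                    cand_edges$protein_b)],
      stringsAsFactors = FALSE
    )
    et$d_value <- et$alpha_cancer - et$alpha_normal
    write_edge_table(et, file.path(config$outdir,
                                   paste0("edge_table_", st$stage, ".tsv")))
    sig <- st$significant
    sif <- cand_edges[cand_edges$protein_a %in% sig &
                        cand_edges$protein_b %in% sig, , drop = FALSE]
    write_sif(sif, file.path(config$outdir,
                             paste0("marker_", st$stage, ".sif")))
  }
  manifest <- list(
    package = "crvnet",
    parameters = unclass(config)[c("pool_alpha", "adjust", "norm_scope",
                                   "t_alpha", "crv_alpha", "n_perm",
                                   "raw_fraction", "stages", "seed")],
    inputs = lapply(unclass(config)[c("expression", "sample_sheet", "ppi")],
                    basename),
    pool_size = nrow(pool),
    candidate_edges = igraph::ecount(candidate),
    significant = lapply(stages, function(s) s$significant),
    core = if (!is.null(markers)) markers$core else character()
  )
  yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))

  invisible(list(config = config, screen = screen, pool = pool,
                 candidate = candidate, A_normal = A_normal,
                 stages = stages, markers = markers))
}
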