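# Average expression, log2 fold change, marker tables, and the end-to-end
# pipeline driver.

test_that("average expression is a plain mean with strict sample checking", {
  m <- rbind(g1 = c(2, 4, 6), g2 = c(1, 1, 10))
  colnames(m) <- c("s1", "s2", "s3")
  expect_equal(unname(average_expression(m, c("s1", "s2"))["g1"]), 3)
  expect_equal(unname(average_expression(m, "s3")["g2"]), 10)
  expect_equal(average_expression(m, c("s1", "s2", "s3")),
               average_expression(m, c("s3", "s1", "s2")))
  expect_error(average_expression(m, character(0)), "empty")
  expect_error(average_expression(m, "nope"), "unknown sample")
})

test_that("log2 fold change handles identity and undefined inputs", {
  expect_equal(log2_fold_change(5, 5), 0)
  expect_equal(log2_fold_change(8, 2), 2)
  expect_true(is.na(log2_fold_change(0, 2)))
  expect_true(is.na(log2_fold_change(3, 0)))
  expect_equal(log2_fold_change(c(2, 4), c(1, 1)), c(1, 2))
})

test_that("published marker rows reproduce their fold changes from averages", {
  rows <- utils::read.delim(system.file("extdata", "hcc_marker_rows.tsv",
                                        package = "crvnet"))
  fc <- log2_fold_change(rows$cancer_avg_exp, rows$control_avg_exp)
  expect_equal(round(fc, 2), rows$log2_fc)
})

test_that("marker tables are sorted by descending CRV with the right columns", {
  m <- rbind(gA = c(10, 20, 5), gB = c(1, 3, 2))
  colnames(m) <- c("c1", "c2", "n1")
  crv <- c(gA = 1.5, gB = 4)
  p <- c(gA = 0.2, gB = 0.001)
  tab <- marker_table(crv, p, m, c("c1", "c2"), "n1",
                      marker_class = c(gB = "core"))
  expect_identical(tab$protein, c("gB", "gA"))
  expect_identical(tab$marker_class, c("core", "none"))
  expect_equal(tab$cancer_avg_exp, c(2, 15))
  expect_equal(tab$log2_fc, log2(c(2 / 2, 15 / 5)))
  expect_identical(names(tab), c("protein", "crv", "p_value",
                                 "cancer_avg_exp", "control_avg_exp",
                                 "log2_fc", "marker_class"))
})

run_tiny_pipeline <- function(outdir, n_perm = 60, seed = 5,
                              dataset_seed = 42L) {
  ds <- generate_dataset(simulation_config(
    n_proteins = 20L, n_early = 15L, n_late = 15L, n_normal = 15L,
    mean_degree = 2, seed = dataset_seed))
  indir <- file.path(outdir, "input")
  write_dataset(ds, indir)
  cfg <- pipeline_config(
    expression = file.path(indir, "expression.tsv"),
    sample_sheet = file.path(indir, "sample_sheet.tsv"),
    ppi = file.path(indir, "candidate_edges.tsv"),
    outdir = file.path(outdir, "out"),
    n_perm = n_perm, seed = seed)
  run_pipeline(cfg)
}

test_that("the pipeline runs end to end and its outputs are well formed", {
  dir <- withr::local_tempdir()
  res <- run_tiny_pipeline(dir)
  out <- file.path(dir, "out")
  files <- list.files(out)
  for (f in c("screen.tsv", "pool.tsv", "manifest.yaml",
              "node_table_early.tsv", "node_table_late.tsv",
              "node_table_total.tsv", "edge_table_early.tsv",
              "marker_early.sif")) {
    expect_true(f %in% files, label = paste(f, "written"))
  }
  nt <- utils::read.delim(file.path(out, "node_table_early.tsv"))
  expect_false(is.unsorted(rev(nt$crv)))
  et <- utils::read.delim(file.path(out, "edge_table_early.tsv"))
  expect_equal(et$d_value, et$alpha_cancer - et$alpha_normal,
               tolerance = 1e-12)
  # every significant protein appears exactly once per stage classification
  if (!is.null(res$markers)) {
    expect_identical(
      length(res$markers$early$proteins),
      sum(res$markers$early$class == "core") +
        sum(res$markers$early$class == "specific"))
  }
})

test_that("identical configuration and seed reproduce outputs byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_tiny_pipeline(d1)
  run_tiny_pipeline(d2)
  files <- list.files(file.path(d1, "out"))
  expect_true(length(files) >= 8)
  for (f in files) {
    expect_identical(readLines(file.path(d1, "out", f)),
                     readLines(file.path(d2, "out", f)),
                     label = paste("file", f))
  }
})

test_that("duplicating the early samples as late gives identical stage tables", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(simulation_config(
    n_proteins = 20L, n_early = 15L, n_late = 15L, n_normal = 15L,
    mean_degree = 2, seed = 24L))
  # replace the late table by a copy of the early one under new sample ids
  ds$expression$late <- ds$expression$early
  colnames(ds$expression$late) <- sub("^E", "L", colnames(ds$expression$early))
  ds$sample_sheet <- data.frame(
    sample_id = c(colnames(ds$expression$early), colnames(ds$expression$late),
                  colnames(ds$expression$normal)),
    condition = rep(c("cancer", "cancer", "normal"), each = 15L),
    stage = rep(c("early", "late", "none"), each = 15L),
    stringsAsFactors = FALSE)
  indir <- file.path(dir, "input")
  write_dataset(ds, indir)
  cfg <- pipeline_config(
    expression = file.path(indir, "expression.tsv"),
    sample_sheet = file.path(indir, "sample_sheet.tsv"),
    ppi = file.path(indir, "candidate_edges.tsv"),
    outdir = file.path(dir, "out"),
    stages = c("early", "late"),
    n_perm = 60, seed = 5)
  run_pipeline(cfg)
  early <- utils::read.delim(file.path(dir, "out", "node_table_early.tsv"))
  late <- utils::read.delim(file.path(dir, "out", "node_table_late.tsv"))
  expect_equal(early[, setdiff(names(early), "marker_class")],
               late[, setdiff(names(late), "marker_class")])
})

test_that("a null dataset fitted at larger n yields (almost) no significant hits", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(simulation_config(
    n_proteins = 25L, n_early = 80L, n_late = 80L, n_normal = 80L,
    mean_degree = 2, differential_edge_fraction = 0, seed = 77L))
  indir <- file.path(dir, "input")
  write_dataset(ds, indir)
  cfg <- pipeline_config(
    expression = file.path(indir, "expression.tsv"),
    sample_sheet = file.path(indir, "sample_sheet.tsv"),
    ppi = file.path(indir, "candidate_edges.tsv"),
    outdir = file.path(dir, "out"),
    stages = "early", n_perm = 400, seed = 9)
  res <- run_pipeline(cfg)
  n_pool <- nrow(res$pool)
  n_sig <- length(res$stages$early$significant)
  # expected alpha * pool size, allow generous binomial slack
  expect_lte(n_sig, stats::qbinom(0.999, n_pool, 0.01) + 1)
})

test_that("pipeline failures name the failing stage", {
  dir <- withr::local_tempdir()
  cfg <- pipeline_config(
    expression = file.path(dir, "missing.tsv"),
    sample_sheet = file.path(dir, "missing2.tsv"),
    ppi = file.path(dir, "missing3.tsv"),
    outdir = file.path(dir, "out"))
  expect_error(suppressWarnings(run_pipeline(cfg)), "read_expression")
})
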