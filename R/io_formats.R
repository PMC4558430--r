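# Readers/writers for expression tables, sample sheets, PPI edge lists and
# Cytoscape-compatible result files. Everything is TSV; outputs are written
# in canonical row/column order so reruns are byte-stable.

write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Read an expression table
#'
#' Expects a TSV with gene identifiers in the first column and sample ids in
#' the header. Values must be numeric and nonnegative (RPKM-like). Rows with
#' duplicated gene ids are collapsed by their mean, with a warning.
#'
#' @param path Path to the TSV file.
#' @return genes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) {
    stop("expression file '", path, "' is empty or has no sample columns")
  }
  genes <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) & vals[[j]] != "NA")
    if (length(bad)) {
      stop("non-numeric expression value '", vals[[j]][bad[1]],
           "' at gene '", genes[bad[1]], "', sample '", names(vals)[j], "'")
    }
    vals[[j]] <- v
  }
  mat <- as.matrix(vals)
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative expression value at gene '", genes[neg[1, 1]],
         "', sample '", colnames(mat)[neg[1, 2]],
         "'; RPKM-like values must be nonnegative")
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dup), " duplicated gene id(s) by mean: ",
            paste(utils::head(dup, 5), collapse = ", "),
            if (length(dup) > 5) ", ..." else "")
    mat <- rowsum(mat, genes)
    mat <- mat / as.vector(table(genes)[rownames(mat)])
  } else {
    rownames(mat) <- genes
  }
  mat
}

#' Write an expression matrix as TSV (inverse of [read_expression()])
#'
#' @param mat genes x samples numeric matrix.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a sample sheet
#'
#' Columns: `sample_id`, `condition` (`cancer`/`normal`), `stage`
#' (`early`/`late`/`none`). Normal samples must have stage `none`.
#'
#' @param path Path to the TSV file.
#' @param expression Optional expression matrix; every expression column
#'   must then have a sheet row.
#' @return Validated data.frame.
#' @export
read_sample_sheet <- function(path, expression = NULL) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  validate_sample_sheet(sheet, expression)
}

validate_sample_sheet <- function(sheet, expression = NULL) {
  need <- c("sample_id", "condition", "stage")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicated sample ids: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "))
  }
  if (!all(sheet$condition %in% c("cancer", "normal"))) {
    stop("condition must be 'cancer' or 'normal'")
  }
  if (!all(sheet$stage %in% c("early", "late", "none"))) {
    stop("stage must be 'early', 'late' or 'none'")
  }
  if (any(sheet$condition == "normal" & sheet$stage != "none")) {
    stop("normal samples must have stage 'none'")
  }
  if (any(sheet$condition == "cancer" & sheet$stage == "none")) {
    stop("cancer samples must have stage 'early' or 'late'")
  }
  if (!is.null(expression)) {
    miss <- setdiff(colnames(expression), sheet$sample_id)
    if (length(miss)) {
      stop("expression column(s) missing from sample sheet: ",
           paste(miss, collapse = ", "))
    }
  }
  sheet
}

#' Write a sample sheet
#' @param sheet data.frame with `sample_id`, `condition`, `stage`.
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  write_tsv(validate_sample_sheet(sheet), path)
}

#' Read an undirected PPI edge list
#'
#' Accepts BioGRID-style TAB exports (default symbol columns
#' `Official Symbol Interactor A`/`B`) as well as plain two-column files.
#' Edges are deduplicated as unordered pairs; self-loops are dropped with a
#' message stating the count.
#'
#' @param path Tab-delimited file with a header row.
#' @param symbol_columns Character pair naming the two endpoint columns.
#' @return data.frame with canonical columns `protein_a`, `protein_b`.
#' @export
read_ppi_edges <- function(path,
                           symbol_columns = c("Official Symbol Interactor A",
                                              "Official Symbol Interactor B")) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      stringsAsFactors = FALSE))
  }
  cols <- symbol_columns
  if (!all(cols %in% names(tab))) {
    if (ncol(tab) == 2L) {
      cols <- names(tab)
    } else {
      stop("edge file lacks column(s) ",
           paste(sQuote(setdiff(symbol_columns, names(tab))), collapse = ", "),
           "; available headers: ", paste(sQuote(names(tab)), collapse = ", "))
    }
  }
  edges <- canonical_edges(tab[[cols[1]]], tab[[cols[2]]])
  n_loops <- attr(edges, "n_self_loops")
  if (n_loops > 0) message("dropped ", n_loops, " self-loop(s)")
  attr(edges, "n_self_loops") <- NULL
  edges
}

node_table_columns <- c("protein", "crv", "p_value", "cancer_avg_exp",
                        "control_avg_exp", "log2_fc", "marker_class")
edge_table_columns <- c("protein_a", "protein_b", "alpha_cancer",
                        "alpha_normal", "d_value")

#' Write a per-protein result table
#'
#' Columns are emitted in the documented order: protein, crv, p_value,
#' cancer_avg_exp, control_avg_exp, log2_fc, marker_class.
#'
#' @param records data.frame containing at least those columns.
#' @param path Output path.
#' @export
write_node_table <- function(records, path) {
  miss <- setdiff(node_table_columns, names(records))
  if (length(miss)) stop("node table lacks column(s): ",
                         paste(miss, collapse = ", "))
  write_tsv(records[, node_table_columns, drop = FALSE], path)
}

#' Write a per-edge result table
#'
#' Columns: protein_a, protein_b, alpha_cancer, alpha_normal, d_value.
#'
#' @param records data.frame containing at least those columns.
#' @param path Output path.
#' @export
write_edge_table <- function(records, path) {
  miss <- setdiff(edge_table_columns, names(records))
  if (length(miss)) stop("edge table lacks column(s): ",
                         paste(miss, collapse = ", "))
  write_tsv(records[, edge_table_columns, drop = FALSE], path)
}

#' Write a network in Cytoscape SIF format
#'
#' One line per undirected edge, `A pp B`. A network without edges yields
#' an empty file.
#'
#' @param edges data.frame whose first two columns are the endpoints.
#' @param path Output path.
#' @export
write_sif <- function(edges, path) {
  lines <- if (nrow(edges)) {
    paste(edges[[1]], "pp", edges[[2]])
  } else {
    character()
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write '", path, "': ", conditionMessage(ok))
  invisible(path)
}
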