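#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then gene symbols.
#'
#' @param path file path.
#' @return named list of unique gene-symbol vectors, with a `description`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(ln, 1, 60))
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of gene-symbol vectors.
#' @param path output path.
#' @param descriptions optional named descriptions (defaults to `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read a region table (TSV: region_id, x, y, z, optional class, block)
#' @param path file path.
#' @return data.frame.
#' @export
read_region_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("region table must have columns ", paste(need, collapse = ", "))
  df
}

#' Read a numeric matrix from TSV (first column = row names)
#' @param path file path.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a numeric matrix to TSV (row names in the first column)
#' @param m matrix. @param path output path.
#' @param rowname_header header for the row-name column.
#' @export
write_matrix_tsv <- function(m, path, rowname_header = "id") {
  df <- data.frame(rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- rowname_header
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic dataset to standard-format files
#'
#' Region table (TSV), per-subject time series (TSV, regions x timepoints),
#' group-mean connectivity matrix (TSV), expression matrix (TSV),
#' annotation and candidate gene sets (GMT), and the ground truth (JSON).
#'
#' @param ds a dataset from [synth_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_synth_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  p <- file.path(dir, "regions.tsv")
  write.table(ds$regions, p, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p)
  for (s in seq_len(dim(ds$ts$values)[1])) {
    m <- ds$ts$values[s, , , drop = TRUE]
    rownames(m) <- ds$regions$region_id
    p <- file.path(dir, sprintf("timeseries_subject%02d.tsv", s))
    write_matrix_tsv(m, p, "region_id")
    files <- c(files, p)
  }
  p <- file.path(dir, "group_connectivity.tsv")
  write_matrix_tsv(ds$group_conn$r, p, "region_id")
  files <- c(files, p)
  p <- file.path(dir, "expression.tsv")
  write_matrix_tsv(ds$expression, p, "gene")
  files <- c(files, p)
  p <- file.path(dir, "annotation.gmt")
  write_gmt(ds$annotation, p)
  files <- c(files, p)
  p <- file.path(dir, "candidate_sets.gmt")
  write_gmt(ds$gene_sets, p)
  files <- c(files, p)
  p <- file.path(dir, "ground_truth.json")
  truth <- ds$truth
  truth$gene_weights <- apply(truth$gene_weights, 2, identity, simplify = FALSE)
  jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA)
  files <- c(files, p)
  invisible(files)
}
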