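#' Read / write an expression matrix as Matrix Market + TSV sidecars
#'
#' The on-disk layout is the conventional triplet: `matrix.mtx` (sparse
#' coordinate format, 1-based indices, genes in rows), `genes.tsv` (one
#' `gene_id` per row) and `cells.tsv` (cell metadata, first column
#' `cell_id`). `read_matrix()` checks that the sidecar row counts match the
#' matrix header and fails loudly otherwise.
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @param layer layer tag to stamp on the values (the format itself does not
#'   record it); default `"raw_counts"`.
#' @return `read_matrix()`: a list with elements `matrix` (an
#'   [expr_matrix]) and `annotation` (a tibble of the cell metadata).
#'   `write_matrix()`: the directory, invisibly.
#' @export
read_matrix <- function(dir, layer = "raw_counts") {
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) abort(paste0("Missing file(s): ", paste(missing, collapse = ", ")))
  m <- Matrix::readMM(paths[1])
  genes <- readr::read_tsv(paths[2], show_col_types = FALSE)
  cells <- readr::read_tsv(paths[3], show_col_types = FALSE)
  if (nrow(genes) != nrow(m)) {
    abort(sprintf("genes.tsv has %d rows but matrix.mtx declares %d genes.",
                  nrow(genes), nrow(m)))
  }
  if (nrow(cells) != ncol(m)) {
    abort(sprintf("cells.tsv has %d rows but matrix.mtx declares %d cells.",
                  nrow(cells), ncol(m)))
  }
  dimnames(m) <- list(genes[[1]], cells[[1]])
  list(matrix = expr_matrix(m, layer = layer), annotation = as_tibble(cells))
}

#' @rdname read_matrix
#' @param matrix an [expr_matrix] to serialize.
#' @param annotation optional cell metadata (first column must be
#'   `cell_id`, matching the matrix columns); a bare `cell_id` table is
#'   written when omitted.
#' @export
write_matrix <- function(matrix, dir, annotation = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(annotation)) {
    annotation <- tibble(cell_id = cell_ids(matrix))
  } else {
    annotation <- validate_annotation(annotation, matrix)
  }
  Matrix::writeMM(matrix$values, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(gene_id = gene_ids(matrix)), file.path(dir, "genes.tsv"))
  readr::write_tsv(annotation, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) abort("Malformed GMT line (need name, description, >=1 gene).")
    unique(parts[-(1:2)])
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' @rdname read_gmt
#' @param sets a named list of character vectors (or a single [gene_set]).
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- setNames(list(sets$genes), sets$name)
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column ortholog map
#'
#' @param path TSV with columns `human_symbol` and `ortholog_symbol` (or any
#'   two columns in that order).
#' @return a tibble with columns `human_symbol`, `ortholog_symbol`,
#'   duplicate pairs removed.
#' @export
read_ortholog_map <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(m) < 2) abort("Ortholog map needs two columns.")
  ortholog_map(m[[1]], m[[2]])
}

#' Construct an ortholog map from paired symbol vectors
#'
#' Many-to-many pairs are allowed; exact duplicate pairs are dropped.
#'
#' @param human_symbol,ortholog_symbol equal-length character vectors.
#' @return a tibble with columns `human_symbol`, `ortholog_symbol`.
#' @export
ortholog_map <- function(human_symbol, ortholog_symbol) {
  stopifnot(length(human_symbol) == length(ortholog_symbol))
  dplyr::distinct(tibble(
    human_symbol = as.character(human_symbol),
    ortholog_symbol = as.character(ortholog_symbol)
  ))
}

#' Read / write a bulk survival cohort
#'
#' A cohort is stored as one TSV: one row per sample, a `sample_id` column,
#' `time` and `event` survival columns, optional clinical covariates, and
#' one column per gene (log2(TPM+1) scale).
#'
#' @param path TSV file path.
#' @param covariates character vector naming non-gene clinical columns.
#' @return `read_cohort()`: a [cohort_data] list.
#' @export
read_cohort <- function(path, covariates = character()) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  cohort_data(tab, covariates = covariates)
}

#' @rdname read_cohort
#' @param cohort a [cohort_data] object.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(as_cohort_table(cohort), path)
  invisible(path)
}
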