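#' Sparse expression matrix container
#'
#' A light S3 wrapper around a sparse gene x cell (or gene x sample) matrix
#' from the Matrix package, tagged with the transformation layer it carries.
#' Layers:
#' \describe{
#'   \item{`raw_counts`}{non-negative integer UMI/read counts}
#'   \item{`lognorm`}{`ln(1 + count / cell_total * scale)` library-size
#'     normalized values (single cell)}
#'   \item{`bulk_log2tpm`}{`log2(TPM + 1)` bulk expression}
#' }
#'
#' @param values a matrix or Matrix with genes in rows and cells/samples in
#'   columns; must carry unique row and column names.
#' @param layer one of `"raw_counts"`, `"lognorm"`, `"bulk_log2tpm"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, layer = c("raw_counts", "lognorm", "bulk_log2tpm")) {
  layer <- match.arg(layer)
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  gene_ids <- rownames(values) %||% (if (nrow(values) == 0) character())
  cell_ids <- colnames(values) %||% (if (ncol(values) == 0) character())
  if (is.null(gene_ids) || is.null(cell_ids)) {
    abort("`values` must have row (gene) and column (cell) names.")
  }
  if (anyDuplicated(gene_ids)) abort("Duplicate gene ids in `values`.")
  if (anyDuplicated(cell_ids)) abort("Duplicate cell ids in `values`.")
  if (layer == "raw_counts") {
    x <- values@x
    if (length(x) && (any(x < 0) || any(x != round(x)))) {
      abort("`raw_counts` layer must contain non-negative integers.")
    }
  }
  structure(list(values = values, layer = layer), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d cells, layer = %s, %.1f%% nonzero\n",
    nrow(x$values), ncol(x$values), x$layer,
    100 * length(x$values@x) / max(1, prod(dim(x$values)))
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and cell identifiers of an expression matrix
#' @param x an [expr_matrix].
#' @return character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
cell_ids <- function(x) colnames(x$values)

#' Subset an expression matrix by gene and/or cell identifiers
#'
#' @param x an [expr_matrix].
#' @param genes,cells character vectors of identifiers to keep (`NULL`
#'   keeps all). Unknown identifiers are an error.
#' @return an [expr_matrix] on the same layer.
#' @export
subset_matrix <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  g <- genes %||% gene_ids(x)
  s <- cells %||% cell_ids(x)
  missing_g <- setdiff(g, gene_ids(x))
  missing_c <- setdiff(s, cell_ids(x))
  if (length(missing_g)) abort(paste0("Unknown genes: ", paste(head(missing_g, 5), collapse = ", ")))
  if (length(missing_c)) abort(paste0("Unknown cells: ", paste(head(missing_c, 5), collapse = ", ")))
  expr_matrix(x$values[g, s, drop = FALSE], layer = x$layer)
}

#' Validate a cell annotation table against an expression matrix
#'
#' Checks the one-row-per-cell contract: `cell_id` must be unique, must
#' match the matrix columns exactly, and `mito_fraction` (if present) must
#' lie in \[0, 1\].
#'
#' @param annotation a data frame with at least a `cell_id` column.
#' @param matrix an [expr_matrix] the annotation describes.
#' @return the annotation as a tibble, rows ordered as the matrix columns.
#' @export
validate_annotation <- function(annotation, matrix) {
  annotation <- as_tibble(annotation)
  if (!"cell_id" %in% names(annotation)) abort("annotation needs a `cell_id` column.")
  if (anyDuplicated(annotation$cell_id)) abort("Duplicate `cell_id` in annotation.")
  if (!setequal(annotation$cell_id, cell_ids(matrix))) {
    abort("annotation `cell_id`s do not match the matrix cells.")
  }
  if ("mito_fraction" %in% names(annotation) &&
      any(annotation$mito_fraction < 0 | annotation$mito_fraction > 1)) {
    abort("`mito_fraction` must lie in [0, 1].")
  }
  annotation[match(cell_ids(matrix), annotation$cell_id), , drop = FALSE]
}
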