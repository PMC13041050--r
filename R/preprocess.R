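#' Quality-control configuration
#'
#' Defaults mirror the conventional single-cell cutoffs used throughout the
#' pipeline: cells with fewer than 500 or more than 7,500 detected genes,
#' or more than 10% mitochondrial counts, are removed (strict
#' inequalities: the boundary values are retained).
#'
#' @param min_genes,max_genes detected-gene bounds (inclusive).
#' @param max_mito maximum mitochondrial fraction (inclusive).
#' @param n_hvg number of highly variable genes for embedding.
#' @param n_pcs number of principal components.
#' @return a `qc_config` list.
#' @export
qc_config <- function(min_genes = 500, max_genes = 7500, max_mito = 0.10,
                      n_hvg = 3000, n_pcs = 15) {
  if (min_genes >= max_genes) abort("`min_genes` must be below `max_genes`.")
  if (n_hvg < 1 || n_pcs < 2) abort("`n_hvg` >= 1 and `n_pcs` >= 2 required.")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito = max_mito, n_hvg = n_hvg, n_pcs = n_pcs),
            class = "qc_config")
}

#' Per-cell QC covariates computed from a raw count matrix
#'
#' Detected genes are counts > 0; the mitochondrial fraction is the count
#' share of genes whose symbol matches `mito_pattern`.
#'
#' @param matrix a raw-count [expr_matrix].
#' @param mito_pattern regex identifying mitochondrial genes.
#' @return tibble: cell_id, n_genes_detected, mito_fraction.
#' @export
cell_qc_metrics <- function(matrix, mito_pattern = "^(MT-|mt-)") {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$layer != "raw_counts") abort("QC metrics need the raw_counts layer.")
  v <- matrix$values
  totals <- Matrix::colSums(v)
  mito <- grepl(mito_pattern, gene_ids(matrix))
  mito_counts <- if (any(mito)) Matrix::colSums(v[mito, , drop = FALSE]) else 0
  tibble(
    cell_id = cell_ids(matrix),
    n_genes_detected = Matrix::colSums(v > 0),
    mito_fraction = ifelse(totals > 0, mito_counts / totals, 0)
  )
}

#' Filter low-quality cells
#'
#' Retains exactly the cells with
#' `min_genes <= n_genes_detected <= max_genes` and
#' `mito_fraction <= max_mito`; genes are untouched. Cells outside these
#' bounds ("fewer than 500 genes", "more than 7,500 genes", "more than 10%
#' mitochondrial counts") are removed. If the annotation lacks the QC
#' columns they are computed from the matrix via [cell_qc_metrics()].
#'
#' @param matrix a raw-count [expr_matrix].
#' @param annotation cell annotation with `cell_id` (QC columns optional).
#' @param qc a [qc_config()].
#' @return list with filtered `matrix` and `annotation` (QC columns
#'   attached).
#' @export
qc_filter <- function(matrix, annotation, qc = qc_config()) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(qc, "qc_config"))
  if (matrix$layer != "raw_counts") abort("qc_filter needs the raw_counts layer.")
  annotation <- validate_annotation(annotation, matrix)
  if (!all(c("n_genes_detected", "mito_fraction") %in% names(annotation))) {
    metrics <- cell_qc_metrics(matrix)
    annotation <- dplyr::left_join(
      annotation[setdiff(names(annotation), c("n_genes_detected", "mito_fraction"))],
      metrics, by = "cell_id"
    )
  }
  keep <- annotation$n_genes_detected >= qc$min_genes &
    annotation$n_genes_detected <= qc$max_genes &
    annotation$mito_fraction <= qc$max_mito
  if (!any(keep)) warn("All cells removed by QC filtering; returning empty matrix.")
  kept <- annotation$cell_id[keep]
  list(
    matrix = expr_matrix(matrix$values[, kept, drop = FALSE], layer = "raw_counts"),
    annotation = annotation[keep, , drop = FALSE]
  )
}

#' Library-size log normalization
#'
#' `value = ln(1 + count / cell_total * scale)`; zero counts stay zero, so
#' sparsity is preserved.
#'
#' @param matrix a raw-count [expr_matrix].
#' @param scale library-size scale factor.
#' @return an [expr_matrix] on the `lognorm` layer.
#' @export
normalize_lognorm <- function(matrix, scale = 1e4) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$layer != "raw_counts") abort("normalize_lognorm needs the raw_counts layer.")
  totals <- Matrix::colSums(matrix$values)
  if (any(totals == 0)) {
    abort(paste0("Cell(s) with zero total counts: ",
                 paste(head(cell_ids(matrix)[totals == 0], 5), collapse = ", ")))
  }
  v <- matrix$values %*% Matrix::Diagonal(x = scale / totals)
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(matrix$values)
  expr_matrix(v, layer = "lognorm")
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log-normalized values and returns
#' the top `n_hvg`; ties are broken by gene label so the selection is
#' deterministic.
#'
#' @param matrix a `lognorm` [expr_matrix].
#' @param n_hvg number of genes to keep; if larger than the universe, all
#'   genes are returned with a warning.
#' @return character vector of gene labels, highest variance first.
#' @export
select_hvg <- function(matrix, n_hvg = 3000) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$layer != "lognorm") abort("select_hvg expects the lognorm layer.")
  v <- matrix$values
  n <- ncol(v)
  mu <- Matrix::rowMeans(v)
  # E[x^2] - mu^2 with the n/(n-1) correction, computed sparsely
  ex2 <- Matrix::rowMeans(v^2)
  vars <- (ex2 - mu^2) * n / max(1, n - 1)
  if (n_hvg > length(vars)) {
    warn(sprintf("n_hvg = %d exceeds the %d-gene universe; returning all genes.",
                 n_hvg, length(vars)))
    n_hvg <- length(vars)
  }
  ord <- order(-vars, gene_ids(matrix))
  gene_ids(matrix)[ord][seq_len(n_hvg)]
}

#' PCA embedding of cells on selected genes
#'
#' Computes principal components of the cells on the given genes after
#' per-gene centering (no unit-variance scaling). The gene means and
#' loadings are retained so query data can be projected into the same
#' space with [project_query()].
#'
#' @param matrix a `lognorm` (or `bulk_log2tpm`) [expr_matrix].
#' @param genes gene labels to embed on (e.g. from [select_hvg()]).
#' @param n_pcs number of components; must not exceed `min(#genes, #cells)`.
#' @return a `pca_embedding` list: `embedding` (cells x n_pcs), `loadings`
#'   (genes x n_pcs), `gene_means`, `explained_variance` (fractions).
#' @export
pca_embed <- function(matrix, genes, n_pcs = 15) {
  stopifnot(inherits(matrix, "expr_matrix"))
  missing_g <- setdiff(genes, gene_ids(matrix))
  if (length(missing_g)) abort(paste0("Genes not in matrix: ", paste(head(missing_g, 5), collapse = ", ")))
  x <- Matrix::t(matrix$values[genes, , drop = FALSE])  # cells x genes
  if (n_pcs > min(dim(x))) {
    abort(sprintf("n_pcs = %d exceeds min(dim) = %d.", n_pcs, min(dim(x))))
  }
  xd <- as.matrix(x)
  pc <- stats::prcomp(xd, center = TRUE, scale. = FALSE, rank. = n_pcs)
  emb <- pc$x[, seq_len(n_pcs), drop = FALSE]
  rownames(emb) <- cell_ids(matrix)
  structure(list(
    embedding = emb,
    loadings = pc$rotation[, seq_len(n_pcs), drop = FALSE],
    gene_means = setNames(pc$center, genes),
    explained_variance = pc$sdev^2 / sum(pc$sdev^2)
  ), class = "pca_embedding")
}
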