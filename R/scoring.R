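#' Bin-controlled module score
#'
#' Per cell: mean log-normalized expression over the gene set minus the
#' mean over control genes drawn (seeded) from matching
#' average-expression bins — `n_ctrl` controls per set gene, sampled from
#' the bin of genes with similar dataset-wide average expression. Genes
#' absent from the matrix are dropped; an empty intersection is an error.
#'
#' @param matrix a `lognorm` [expr_matrix].
#' @param genes the gene set (character).
#' @param n_bins number of average-expression bins.
#' @param n_ctrl control genes sampled per set gene.
#' @param seed integer seed for the control draw.
#' @return a `score_vector` tibble: `cell_id`, `score`, with attributes
#'   `method` and `scaled`.
#' @export
module_score <- function(matrix, genes, n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$layer != "lognorm") abort("module_score expects the lognorm layer.")
  genes <- intersect(unique(genes), gene_ids(matrix))
  if (!length(genes)) abort("Gene set has empty intersection with the matrix.")
  avg <- Matrix::rowMeans(matrix$values)
  n_bins <- min(n_bins, length(unique(avg)))
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bin) <- gene_ids(matrix)
  ctrl <- local_rng(seed, {
    unique(unlist(lapply(genes, function(g) {
      pool <- names(bin)[bin == bin[g]]
      sample(pool, min(n_ctrl, length(pool)))
    })))
  })
  set_mean <- Matrix::colMeans(matrix$values[genes, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(matrix$values[ctrl, , drop = FALSE])
  score_vector(cell_ids(matrix), set_mean - ctrl_mean, method = "module_score")
}

#' Single-sample GSEA scores
#'
#' Per sample, the rank-weighted running-sum enrichment statistic: genes
#' are ranked by expression, in-set steps are weighted by
#' `|rank|^alpha` and out-of-set steps by `1/(n_genes - n_set)`; the score
#' is the sum of the running-sum differences. Raw scores are then divided
#' by their range across samples (per set) unless `normalize = FALSE`.
#' Depends on expression only through ranks, so any strictly monotone
#' per-sample transform leaves scores unchanged.
#'
#' @param matrix a `bulk_log2tpm` or `lognorm` [expr_matrix].
#' @param gene_sets named list of gene vectors (sets smaller than 2 genes
#'   draw a warning).
#' @param alpha rank-weight exponent.
#' @param normalize divide by the per-set score range across samples.
#' @return tibble: `sample_id`, one column per gene set.
#' @export
ssgsea <- function(matrix, gene_sets, alpha = 0.25, normalize = TRUE) {
  stopifnot(inherits(matrix, "expr_matrix"))
  genes <- gene_ids(matrix)
  x <- as.matrix(matrix$values)
  n <- length(genes)
  out <- tibble(sample_id = cell_ids(matrix))
  for (nm in names(gene_sets)) {
    gs <- intersect(unique(gene_sets[[nm]]), genes)
    if (length(gs) < 2) warn(sprintf("Gene set %s has fewer than 2 genes in the matrix.", nm))
    if (!length(gs)) {
      out[[nm]] <- NA_real_
      next
    }
    in_set <- genes %in% gs
    scores <- vapply(seq_len(ncol(x)), function(j) {
      ord <- order(x[, j], decreasing = TRUE)
      inset_ord <- in_set[ord]
      # rank weights: position from the top, weighted by rank^alpha
      r <- seq_len(n)
      w <- (n - r + 1)^alpha
      pos <- cumsum(ifelse(inset_ord, w, 0)) / sum(w[inset_ord])
      neg <- cumsum(ifelse(inset_ord, 0, 1)) / (n - sum(in_set))
      sum(pos - neg)
    }, numeric(1))
    if (normalize) {
      rng <- diff(range(scores))
      if (rng > 0) scores <- scores / rng
    }
    out[[nm]] <- scores
  }
  out
}

#' Construct a score vector
#'
#' @param ids cell or sample identifiers.
#' @param score numeric scores.
#' @param method scoring method tag.
#' @param scaled whether the scores have been 0-1 rescaled.
#' @return a `score_vector` tibble.
#' @export
score_vector <- function(ids, score, method = "module_score", scaled = FALSE) {
  out <- tibble(cell_id = ids, score = as.numeric(score))
  attr(out, "method") <- method
  attr(out, "scaled") <- scaled
  class(out) <- c("score_vector", class(tibble()))
  out
}

#' Rescale scores to the 0-1 range
#'
#' `(x - min) / (max - min)`; constant input maps to all zeros (documented
#' convention). Idempotent.
#'
#' @param scores a numeric vector or `score_vector` tibble.
#' @return same shape as the input, rescaled.
#' @export
scale01 <- function(scores) {
  if (inherits(scores, "score_vector") || is.data.frame(scores)) {
    out <- scores
    out$score <- scale01(scores$score)
    attr(out, "scaled") <- TRUE
    return(out)
  }
  if (!length(scores)) abort("Need at least one score.")
  rng <- range(scores)
  if (rng[1] == rng[2]) return(rep(0, length(scores)))
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Composite enrichment ratio
#'
#' `(numerator + eps) / (denominator + eps)` on 0-1 scaled scores — the
#' form used for the M1/M2 macrophage polarization ratio and the
#' pro-tumor/anti-tumor cytokine ratio. The epsilon guard keeps the value
#' finite at zero denominators.
#'
#' @param num,den `score_vector` tibbles over the same samples (order and
#'   identity checked).
#' @param eps stabilizer added to both terms.
#' @param rescale 0-1 rescale both inputs first (default `TRUE`).
#' @return tibble: `cell_id`, `value`.
#' @export
composite_ratio <- function(num, den, eps = 1e-6, rescale = TRUE) {
  if (!identical(num$cell_id, den$cell_id)) abort("Numerator and denominator samples are misaligned.")
  a <- if (rescale) scale01(num$score) else num$score
  b <- if (rescale) scale01(den$score) else den$score
  tibble(cell_id = num$cell_id, value = (a + eps) / (b + eps))
}

#' Mean expression of a gene pair
#'
#' Per-sample arithmetic mean of two genes' expression — the
#' ligand-receptor signal proxy (e.g. ANXA1 with FPR1 or FPR2).
#'
#' @param matrix an [expr_matrix].
#' @param gene_a,gene_b gene labels (an error names any missing gene).
#' @return a `score_vector` tibble.
#' @export
pair_mean_expression <- function(matrix, gene_a, gene_b) {
  stopifnot(inherits(matrix, "expr_matrix"))
  for (g in c(gene_a, gene_b)) {
    if (!g %in% gene_ids(matrix)) abort(paste0("Gene not in matrix: ", g))
  }
  vals <- (matrix$values[gene_a, ] + matrix$values[gene_b, ]) / 2
  score_vector(cell_ids(matrix), as.numeric(vals), method = "pair_mean")
}

#' Fraction of gene-positive cells
#'
#' Fraction of the subset cells with raw count strictly above zero for the
#' gene — the sparsity-robust "gene-positive" rule.
#'
#' @param matrix a raw-count [expr_matrix].
#' @param gene gene label.
#' @param cell_subset cell ids to evaluate (default all; empty is an
#'   error).
#' @return a single fraction in \[0, 1\].
#' @export
gene_positive_fraction <- function(matrix, gene, cell_subset = NULL) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$layer != "raw_counts") abort("gene_positive_fraction needs the raw_counts layer.")
  if (!gene %in% gene_ids(matrix)) abort(paste0("Gene not in matrix: ", gene))
  cell_subset <- cell_subset %||% cell_ids(matrix)
  if (!length(cell_subset)) abort("Empty cell subset.")
  bad <- setdiff(cell_subset, cell_ids(matrix))
  if (length(bad)) abort(paste0("Unknown cells: ", paste(head(bad, 5), collapse = ", ")))
  mean(matrix$values[gene, cell_subset] > 0)
}
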