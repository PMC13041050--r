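#' Two-group marker detection
#'
#' Per-gene two-group test with the fold-change convention used for marker
#' screens: for `lognorm` data the log2 fold change is
#' `log2((mean(expm1(A)) + 1) / (mean(expm1(B)) + 1))` (pseudocount 1,
#' back-transformed means); for `bulk_log2tpm` data it is the difference of
#' group means. Tests: Wilcoxon rank-sum (single cell) or Welch t (bulk
#' surrogate). P values are adjusted by Bonferroni or Benjamini-Hochberg.
#'
#' @param matrix an [expr_matrix] on the `lognorm` or `bulk_log2tpm` layer.
#' @param group_labels per-cell labels with exactly two levels.
#' @param group_a the level treated as group A (positive fold change when
#'   higher in A); default the first sorted level.
#' @param test `"wilcoxon"` or `"welch"`.
#' @param adjust `"bh"` or `"bonferroni"`.
#' @return a `deg_table` tibble: `gene`, `log2_fc`, `p_value`, `p_adj`,
#'   `adjust_method`, `direction` (`"up"` when log2_fc > 0).
#' @export
rank_markers <- function(matrix, group_labels, group_a = NULL,
                         test = c("wilcoxon", "welch"),
                         adjust = c("bh", "bonferroni")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  stopifnot(inherits(matrix, "expr_matrix"))
  if (!matrix$layer %in% c("lognorm", "bulk_log2tpm")) {
    abort("rank_markers needs the lognorm or bulk_log2tpm layer.")
  }
  group_labels <- as.character(group_labels)
  stopifnot(length(group_labels) == ncol(matrix$values))
  levels <- sort(unique(group_labels))
  if (length(levels) != 2) abort("Exactly two groups are required.")
  group_a <- group_a %||% levels[1]
  if (!group_a %in% levels) abort("`group_a` is not one of the group labels.")
  group_b <- setdiff(levels, group_a)
  in_a <- group_labels == group_a
  in_b <- group_labels == group_b
  if (sum(in_a) < 2 || sum(in_b) < 2) abort("Each group needs at least 2 cells.")
  x <- as.matrix(matrix$values)
  stats_per_gene <- map(seq_len(nrow(x)), function(g) {
    a <- x[g, in_a]
    b <- x[g, in_b]
    fc <- if (matrix$layer == "lognorm") {
      log2((mean(expm1(a)) + 1) / (mean(expm1(b)) + 1))
    } else {
      mean(a) - mean(b)
    }
    p <- if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) {
      1
    } else if (test == "wilcoxon") {
      suppressWarnings(wilcox.test(a, b)$p.value)
    } else {
      tryCatch(t.test(a, b)$p.value, error = function(e) 1)
    }
    c(fc = fc, p = p)
  })
  fc <- map_dbl(stats_per_gene, 1)
  p <- map_dbl(stats_per_gene, 2)
  p_adj <- p.adjust(p, method = if (adjust == "bh") "BH" else "bonferroni")
  structure(
    tibble(
      gene = gene_ids(matrix),
      log2_fc = fc,
      p_value = p,
      p_adj = p_adj,
      adjust_method = adjust,
      direction = ifelse(fc > 0, "up", ifelse(fc < 0, "down", "none"))
    ),
    class = c("deg_table", class(tibble()))
  )
}

#' Threshold specification for DEG filtering
#'
#' Carries the printed cutoffs used at the different pipeline stages, e.g.
#' log2 fold change above 1.5 with adjusted p below 0.01 for the
#' young-vs-old tumor contrast, 0.5/0.01 for tumor-vs-normal, 0.1/0.05 for
#' the cross-species aging contrast. Both inequalities are strict.
#'
#' @param log2fc_min minimum log2 fold change (exclusive).
#' @param padj_max maximum adjusted p value (exclusive), in (0, 1\].
#' @param absolute if `TRUE`, threshold `|log2_fc|` instead of the signed
#'   value.
#' @return a `threshold_spec` list.
#' @export
threshold_spec <- function(log2fc_min, padj_max, absolute = FALSE) {
  if (padj_max <= 0 || padj_max > 1) abort("`padj_max` must lie in (0, 1].")
  structure(list(log2fc_min = log2fc_min, padj_max = padj_max,
                 absolute = absolute), class = "threshold_spec")
}

#' Filter a DEG table by thresholds and direction
#'
#' Retains genes with `log2_fc > log2fc_min` (or `|log2_fc| > log2fc_min`
#' when `absolute`) and `p_adj < padj_max` — both strict — restricted to
#' the requested direction.
#'
#' @param table a `deg_table` from [rank_markers()].
#' @param spec a [threshold_spec()].
#' @param direction `"up"`, `"down"`, or `"both"`.
#' @param name name for the resulting gene set.
#' @return a [gene_set].
#' @export
filter_degs <- function(table, spec, direction = c("up", "down", "both"),
                        name = "degs") {
  direction <- match.arg(direction)
  stopifnot(inherits(spec, "threshold_spec"))
  fc <- if (spec$absolute) abs(table$log2_fc) else table$log2_fc
  keep <- fc > spec$log2fc_min & table$p_adj < spec$padj_max
  keep <- keep & switch(direction,
    up = table$log2_fc > 0,
    down = table$log2_fc < 0,
    both = TRUE
  )
  gene_set(
    name = name,
    genes = table$gene[keep],
    provenance = sprintf("filter_degs(log2fc_min=%g, padj_max=%g, absolute=%s, direction=%s)",
                         spec$log2fc_min, spec$padj_max, spec$absolute, direction)
  )
}
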