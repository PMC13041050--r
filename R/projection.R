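#' Project query cells into a reference principal-component space
#'
#' Centers the query expression with the *reference* gene means and applies
#' the reference loadings, so reference and query cells share one
#' coordinate system. Genes absent from the query are dropped from the
#' loadings (with a warning below 50 shared genes; an error at zero).
#'
#' @param ref_pca a `pca_embedding` from [pca_embed()] on the reference.
#' @param query_matrix a [expr_matrix] on the same layer the reference was
#'   embedded on.
#' @param shared_genes optional explicit gene subset; default is the
#'   intersection of the loading genes with the query universe.
#' @return a cells x n_pcs matrix of query coordinates.
#' @export
project_query <- function(ref_pca, query_matrix, shared_genes = NULL) {
  stopifnot(inherits(ref_pca, "pca_embedding"), inherits(query_matrix, "expr_matrix"))
  loading_genes <- rownames(ref_pca$loadings)
  shared <- shared_genes %||% intersect(loading_genes, gene_ids(query_matrix))
  if (!length(shared)) abort("No shared genes between reference loadings and query.")
  if (length(shared) < 50) {
    warn(sprintf("Only %d shared genes; the projection may be unstable.", length(shared)))
  }
  x <- Matrix::t(query_matrix$values[shared, , drop = FALSE])
  centered <- sweep(as.matrix(x), 2, ref_pca$gene_means[shared], "-")
  emb <- centered %*% ref_pca$loadings[shared, , drop = FALSE]
  rownames(emb) <- cell_ids(query_matrix)
  emb
}

# Row-wise k nearest neighbors of `from` among `to` (Euclidean), blockwise.
# Returns an integer matrix nrow(from) x k of indices into `to`.
knn_index <- function(from, to, k, exclude_self = FALSE) {
  k <- min(k, nrow(to) - as.integer(exclude_self))
  out <- matrix(0L, nrow(from), k)
  to_sq <- rowSums(to^2)
  block <- max(1L, floor(2e7 / nrow(to)))
  for (start in seq(1L, nrow(from), by = block)) {
    idx <- start:min(start + block - 1L, nrow(from))
    d2 <- outer(rowSums(from[idx, , drop = FALSE]^2), to_sq, "+") -
      2 * from[idx, , drop = FALSE] %*% t(to)
    for (j in seq_along(idx)) {
      dj <- d2[j, ]
      if (exclude_self) dj[idx[j]] <- Inf
      out[idx[j], ] <- order(dj)[seq_len(k)]
    }
  }
  out
}

#' Find mutual-nearest-neighbor anchors between reference and query
#'
#' A pair (r, q) is an anchor when r is among the `k_anchor` nearest
#' reference neighbors of q and q is among the `k_anchor` nearest query
#' neighbors of r, in the shared embedding. Each anchor is scored by
#' shared-neighbor consistency: the overlap of the two cells'
#' `k_score`-nearest-neighborhoods in the pooled embedding, quantile-
#' rescaled to \[0, 1\] (constant raw scores map to 1).
#'
#' @param ref_embedding,query_embedding coordinate matrices with cell ids
#'   as row names (reference may be a `pca_embedding`).
#' @param k_anchor neighbors considered for mutuality.
#' @param k_score neighborhood size for the consistency score.
#' @return an `anchor_set`: tibble with `ref_cell`, `query_cell`, `score`.
#' @export
find_anchors <- function(ref_embedding, query_embedding, k_anchor = 5, k_score = 30) {
  if (inherits(ref_embedding, "pca_embedding")) ref_embedding <- ref_embedding$embedding
  ref <- as.matrix(ref_embedding)
  qry <- as.matrix(query_embedding)
  stopifnot(ncol(ref) == ncol(qry))
  nn_q_of_r <- knn_index(ref, qry, k_anchor)   # per ref cell: nearest query cells
  nn_r_of_q <- knn_index(qry, ref, k_anchor)   # per query cell: nearest ref cells
  pairs <- list_rbind(map(seq_len(nrow(ref)), function(r) {
    qs <- nn_q_of_r[r, ]
    mutual <- qs[vapply(qs, function(q) r %in% nn_r_of_q[q, ], logical(1))]
    if (!length(mutual)) return(NULL)
    tibble(ref_idx = r, query_idx = mutual)
  }))
  if (is.null(pairs) || !nrow(pairs)) {
    warn("No mutual nearest neighbors found; empty anchor set.")
    return(structure(tibble(ref_cell = character(), query_cell = character(),
                            score = numeric()), class = c("anchor_set", class(tibble()))))
  }
  pooled <- rbind(ref, qry)
  ks <- min(k_score, nrow(pooled) - 1L)
  need <- unique(c(pairs$ref_idx, nrow(ref) + pairs$query_idx))
  nn_pooled <- matrix(0L, nrow(pooled), ks)
  nn_pooled[need, ] <- knn_index(pooled[need, , drop = FALSE], pooled, ks,
                                 exclude_self = FALSE)
  # exclude_self would need global indices; drop self matches manually
  raw <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- setdiff(nn_pooled[pairs$ref_idx[i], ], pairs$ref_idx[i])
    b <- setdiff(nn_pooled[nrow(ref) + pairs$query_idx[i], ], nrow(ref) + pairs$query_idx[i])
    length(intersect(a, b))
  }, numeric(1))
  lo <- stats::quantile(raw, 0.01)
  hi <- stats::quantile(raw, 0.90)
  score <- if (hi > lo) pmin(1, pmax(0, (raw - lo) / (hi - lo))) else rep(1, length(raw))
  structure(
    tibble(ref_cell = rownames(ref)[pairs$ref_idx],
           query_cell = rownames(qry)[pairs$query_idx],
           score = score),
    class = c("anchor_set", class(tibble()))
  )
}

#' Transfer categorical labels from reference to query through anchors
#'
#' For each query cell, its `k_weight` nearest anchors (by distance to the
#' anchor's query-side cell in the embedding) are weighted by a Gaussian
#' kernel with adaptive bandwidth set to a third of the distance to the
#' `k_weight`-th anchor — so the kernel has effectively vanished (weight
#' about 1e-4) at the edge of the anchor neighborhood — multiplied by the
#' anchor score and normalized to sum 1. Per-label
#' probability is the weight mass of anchors whose reference cell carries
#' that label; the projected label is the argmax (ties broken
#' lexicographically and flagged) and the reported score is the maximum
#' probability. Cell type and age label are transferred independently.
#' Query cells with no reachable anchor (all weights zero) are labeled
#' `"unassigned"` with score 0.
#'
#' @param anchors an `anchor_set` from [find_anchors()].
#' @param ref_annotation reference cell annotation with `cell_id`,
#'   `cell_type` and `age_label` columns.
#' @param query_embedding query coordinate matrix (row names = cell ids).
#' @param k_weight anchors per query cell.
#' @return a `projection_result` tibble: `cell_id`,
#'   `projected_cell_type`, `cell_type_score`, `projected_age`,
#'   `transfer_score` (age-label max probability), `tie_flag`.
#' @export
transfer_labels <- function(anchors, ref_annotation, query_embedding, k_weight = 50) {
  if (!nrow(anchors)) abort("Empty anchor set; cannot transfer labels.")
  ref_annotation <- as_tibble(ref_annotation)
  stopifnot(all(c("cell_id", "cell_type", "age_label") %in% names(ref_annotation)))
  qry <- as.matrix(query_embedding)
  anchor_q <- qry[anchors$query_cell, , drop = FALSE]
  anchor_type <- ref_annotation$cell_type[match(anchors$ref_cell, ref_annotation$cell_id)]
  anchor_age <- ref_annotation$age_label[match(anchors$ref_cell, ref_annotation$cell_id)]
  k <- min(k_weight, nrow(anchors))
  rows <- map(seq_len(nrow(qry)), function(i) {
    d2 <- rowSums(sweep(anchor_q, 2, qry[i, ], "-")^2)
    near <- order(d2)[seq_len(k)]
    sigma2 <- d2[near[k]] / 9  # sd = d_k / 3: kernel ~1e-4 at the k-th anchor
    kern <- if (sigma2 > 0) exp(-d2[near] / sigma2) else rep(1, k)
    w <- kern * anchors$score[near]
    if (sum(w) == 0) {
      return(tibble(cell_id = rownames(qry)[i],
                    projected_cell_type = "unassigned", cell_type_score = 0,
                    projected_age = "unassigned", transfer_score = 0,
                    tie_flag = FALSE))
    }
    w <- w / sum(w)
    vote <- function(labels) {
      p <- vapply(split(w, labels[near]), sum, numeric(1))
      p <- sort(p, decreasing = TRUE)
      top <- names(p)[p == p[1]]
      list(label = sort(top)[1], score = unname(p[1]), tie = length(top) > 1)
    }
    vt <- vote(anchor_type)
    va <- vote(anchor_age)
    tibble(cell_id = rownames(qry)[i],
           projected_cell_type = vt$label, cell_type_score = vt$score,
           projected_age = va$label, transfer_score = va$score,
           tie_flag = vt$tie || va$tie)
  })
  structure(list_rbind(rows),
            class = c("projection_result", class(tibble())))
}

#' Age-bin rule: partition reference age labels into young and old
#'
#' @param age_levels the full ordered reference label set.
#' @param young_set labels mapped to "young"; default GW7-GW14 (inclusive),
#'   the early-embryonic stage; the complement (GW16 onward) is "old".
#' @return an `age_bin_rule` list.
#' @export
age_bin_rule <- function(age_levels, young_set = young_age_levels(age_levels)) {
  if (!all(young_set %in% age_levels)) abort("`young_set` must be a subset of `age_levels`.")
  structure(list(age_levels = age_levels, young_set = young_set),
            class = "age_bin_rule")
}

#' Bin projected gestational-week labels into young vs old
#'
#' Adds an `age_bin` column: `"young"` iff the projected age lies in the
#' rule's young set, `"old"` otherwise; `"unassigned"` cells get `NA`.
#' Projected ages outside the reference label set are an error.
#'
#' @param result a `projection_result` from [transfer_labels()].
#' @param rule an [age_bin_rule()].
#' @return the result tibble with an `age_bin` column.
#' @export
bin_projected_age <- function(result, rule) {
  stopifnot(inherits(rule, "age_bin_rule"))
  known <- c(rule$age_levels, "unassigned")
  bad <- setdiff(unique(result$projected_age), known)
  if (length(bad)) {
    abort(paste0("Projected age label(s) outside the reference set: ",
                 paste(bad, collapse = ", ")))
  }
  result$age_bin <- dplyr::case_when(
    result$projected_age == "unassigned" ~ NA_character_,
    result$projected_age %in% rule$young_set ~ "young",
    TRUE ~ "old"
  )
  result
}
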