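#' Multiplicative-update non-negative matrix factorization
#'
#' Lee-Seung Frobenius updates from a seeded random start, best of
#' `n_restarts` runs kept (lowest reconstruction error). Convergence:
#' relative loss change below `tol` or `max_iter` iterations.
#'
#' @param v non-negative genes x cells matrix.
#' @param k factorization rank.
#' @param seed integer seed (restart r uses `seed + r`).
#' @param n_restarts random restarts.
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @return list: `w` (genes x k), `h` (k x cells), `loss`.
#' @export
nmf_factorize <- function(v, k, seed = 1L, n_restarts = 5, tol = 1e-6,
                          max_iter = 500) {
  stopifnot(k >= 1, all(v >= 0))
  eps <- 1e-12
  best <- NULL
  for (r in seq_len(n_restarts)) {
    local_rng(seed + r, {
      w <- matrix(runif(nrow(v) * k), nrow(v), k)
      h <- matrix(runif(k * ncol(v)), k, ncol(v))
      loss_prev <- Inf
      for (it in seq_len(max_iter)) {
        h <- h * (crossprod(w, v)) / (crossprod(w, w %*% h) + eps)
        w <- w * (v %*% t(h)) / (w %*% tcrossprod(h) + eps)
        if (it %% 10 == 0 || it == max_iter) {
          loss <- sqrt(sum((v - w %*% h)^2))
          if (is.finite(loss_prev) && abs(loss_prev - loss) <= tol * max(loss_prev, eps)) break
          loss_prev <- loss
        }
      }
      loss <- sqrt(sum((v - w %*% h)^2))
      if (is.null(best) || loss < best$loss) {
        rownames(w) <- rownames(v)
        best <- list(w = w, h = h, loss = loss)
      }
    })
  }
  best
}

#' Per-sample NMF programs
#'
#' For each sample and each rank in `k_values`, factorizes the sample's
#' cells and emits every factor column as a program of non-negative gene
#' weights. By default the lognorm values are centered per gene within
#' the sample and negative values are clipped at zero (count logged), so
#' factors describe above-average expression programs rather than the
#' shared baseline profile. All-zero samples are skipped with a warning.
#'
#' @param matrix a `lognorm` [expr_matrix].
#' @param annotation cell annotation with `cell_id` and the sample column.
#' @param sample_col name of the sample column.
#' @param k_values ranks to factorize at (default 4, 5, 6).
#' @param center center per gene before clipping (default `TRUE`).
#' @param seed base seed.
#' @param n_restarts,tol,max_iter passed to [nmf_factorize()].
#' @return an `nmf_programs` list; each element has `sample_id`, `k_used`,
#'   `weights` (named non-negative vector).
#' @export
nmf_programs_per_sample <- function(matrix, annotation, sample_col = "sample",
                                    k_values = c(4, 5, 6), center = TRUE,
                                    seed = 1L, n_restarts = 5, tol = 1e-6,
                                    max_iter = 500) {
  stopifnot(inherits(matrix, "expr_matrix"))
  annotation <- validate_annotation(annotation, matrix)
  samples <- unique(annotation[[sample_col]])
  programs <- list()
  for (s in samples) {
    cells <- annotation$cell_id[annotation[[sample_col]] == s]
    v <- as.matrix(matrix$values[, cells, drop = FALSE])
    if (center) v <- v - rowMeans(v)
    n_neg <- sum(v < 0)
    if (n_neg) {
      inform(sprintf("Sample %s: clipped %d negative values to 0.", s, n_neg))
      v[v < 0] <- 0
    }
    if (all(v == 0)) {
      warn(sprintf("Sample %s is all-zero; skipped.", s))
      next
    }
    for (k in k_values) {
      fit <- nmf_factorize(v, k, seed = seed + 1000L * match(s, samples) + k,
                           n_restarts = n_restarts, tol = tol, max_iter = max_iter)
      for (j in seq_len(k)) {
        if (all(fit$w[, j] == 0)) next
        programs[[length(programs) + 1L]] <- list(
          sample_id = s, k_used = k, weights = fit$w[, j]
        )
      }
    }
  }
  structure(programs, class = "nmf_programs")
}

# Relative weight of each gene within a program (weight / program max).
relative_weights <- function(weights) weights / max(weights)

#' Consensus meta-programs from per-sample NMF programs
#'
#' Each program is first reduced to its `n_top` highest-weight genes
#' (weights elsewhere set to zero) — NMF factors all carry the dense
#' baseline expression component, and without the truncation that shared
#' baseline dominates every pairwise similarity. The truncated programs
#' are clustered by average linkage on cosine similarity; a cluster merges
#' while its average similarity stays above `cosine_min`. Clusters
#' spanning at least two samples become meta-programs. Per gene within a
#' meta-program: the explanatory power is its mean relative weight (weight
#' over program max, after truncation) across member programs, and the
#' confidence is the fraction of member programs where the relative
#' weight exceeds `weight_ratio_min`. The consensus gene list holds genes
#' with confidence above 0.5 (a majority of members); meta-programs whose
#' list has `min_genes` genes or fewer are discarded ("more than 10" is
#' strict).
#'
#' @param programs an `nmf_programs` list (>= 2 programs).
#' @param cosine_min cosine-similarity threshold for merging.
#' @param min_genes strict lower bound on the consensus gene list.
#' @param n_top genes kept per program before similarity/consensus.
#' @param weight_ratio_min relative-weight cutoff for a gene to "appear"
#'   in a member program.
#' @return a `meta_programs` list; each element has `mp_id`, `members`
#'   (tibble `sample_id`, `k_used`), `gene_stats` (tibble `gene`, `power`,
#'   `confidence`) and `consensus_genes`.
#' @export
consensus_metaprograms <- function(programs, cosine_min = 0.7, min_genes = 10,
                                   n_top = 50, weight_ratio_min = 0.25) {
  if (length(programs) < 2) abort("Need at least 2 programs for a consensus.")
  genes <- sort(unique(unlist(lapply(programs, function(p) names(p$weights)))))
  w <- vapply(programs, function(p) {
    out <- setNames(numeric(length(genes)), genes)
    full <- p$weights
    keep <- names(sort(full, decreasing = TRUE))[seq_len(min(n_top, sum(full > 0)))]
    out[keep] <- full[keep]
    out
  }, numeric(length(genes)))
  norms <- sqrt(colSums(w^2))
  cosine <- crossprod(sweep(w, 2, pmax(norms, 1e-12), "/"))
  hc <- stats::hclust(stats::as.dist(1 - cosine), method = "average")
  cluster <- stats::cutree(hc, h = 1 - cosine_min)
  mps <- list()
  for (cl in sort(unique(cluster))) {
    members <- which(cluster == cl)
    samples <- unique(vapply(programs[members], `[[`, character(1), "sample_id"))
    if (length(samples) < 2) next
    rel <- vapply(members, function(i) relative_weights(w[, i]), numeric(length(genes)))
    gene_stats <- tibble(
      gene = genes,
      power = unname(rowMeans(rel)),
      confidence = unname(rowMeans(rel > weight_ratio_min))
    )
    consensus <- gene_stats$gene[gene_stats$confidence > 0.5]
    if (length(consensus) <= min_genes) next
    mps[[length(mps) + 1L]] <- list(
      mp_id = sprintf("MP%d", length(mps) + 1L),
      members = list_rbind(map(programs[members], function(p) {
        tibble(sample_id = p$sample_id, k_used = p$k_used)
      })),
      gene_stats = gene_stats,
      consensus_genes = consensus
    )
  }
  if (!length(mps)) warn("No cluster spans two samples; no meta-programs.")
  structure(mps, class = "meta_programs")
}

#' Select meta-program feature genes by power and confidence
#'
#' Retains genes whose explanatory power strictly exceeds `power_min` and
#' whose confidence strictly exceeds `confidence_min`.
#'
#' @param mp one element of [consensus_metaprograms()] output (>= 2
#'   member programs).
#' @param power_min,confidence_min strict thresholds (defaults 0.5, 0.7).
#' @return a [gene_set].
#' @export
select_mp_genes <- function(mp, power_min = 0.5, confidence_min = 0.7) {
  if (nrow(mp$members) < 2) abort("Meta-program needs at least 2 member programs.")
  keep <- mp$gene_stats$power > power_min & mp$gene_stats$confidence > confidence_min
  gene_set(mp$mp_id, mp$gene_stats$gene[keep],
           provenance = sprintf("select_mp_genes(power>%g, confidence>%g)",
                                power_min, confidence_min))
}

#' Per-cell meta-program scores
#'
#' Scores every meta-program's gene set on every cell with the
#' bin-controlled [module_score()].
#'
#' @param matrix a `lognorm` [expr_matrix].
#' @param mp_gene_sets named list of gene vectors (or [gene_set]s).
#' @param ... passed to [module_score()].
#' @return tibble: `cell_id`, one score column per meta-program.
#' @export
score_mp_per_cell <- function(matrix, mp_gene_sets, ...) {
  out <- tibble(cell_id = cell_ids(matrix))
  for (nm in names(mp_gene_sets)) {
    gs <- mp_gene_sets[[nm]]
    if (inherits(gs, "gene_set")) gs <- gs$genes
    out[[nm]] <- module_score(matrix, gs, ...)$score
  }
  out
}
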