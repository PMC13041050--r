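# Shared fixture builders. All synthetic, generated in code at test time.

# Small simulation config that keeps every planted program but runs fast.
small_config <- function(n_genes = 600, n_cells_per_group = 30, seed = 42L, ...) {
  simulation_config(n_genes = n_genes, n_cells_per_group = n_cells_per_group,
                    seed = seed, ...)
}

# Dense toy expression matrix with explicit values.
toy_matrix <- function(values, layer = "lognorm",
                       genes = sprintf("g%d", seq_len(nrow(values))),
                       cells = sprintf("c%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, cells)
  expr_matrix(values, layer = layer)
}

# lognorm matrix of i.i.d. values for null scoring checks.
iid_lognorm <- function(n_genes, n_cells, seed = 1) {
  withr::with_seed(seed, {
    toy_matrix(matrix(abs(rnorm(n_genes * n_cells)), n_genes, n_cells),
               genes = sprintf("GENE%04d", seq_len(n_genes)))
  })
}

# Pseudo-bulk log2 expression profiles from a raw-count matrix: pools of
# `cells_per_sample` cells aggregated to counts-per-million and transformed
# as log2(CPM + 1) (the TPM-like bulk scale; synthetic genes share one
# length).
pseudo_bulk <- function(matrix, cells, n_samples, cells_per_sample, prefix, seed) {
  withr::with_seed(seed, {
    profiles <- vapply(seq_len(n_samples), function(i) {
      pool <- sample(cells, cells_per_sample)
      tot <- Matrix::rowSums(matrix$values[, pool, drop = FALSE])
      log2(tot / sum(tot) * 1e6 + 1)
    }, numeric(nrow(matrix$values)))
    colnames(profiles) <- sprintf("%s%02d", prefix, seq_len(n_samples))
    rownames(profiles) <- gene_ids(matrix)
    profiles
  })
}

# End-to-end signature-derivation fixture at reduced size, shared by the
# signature unit test and reused (at full size) in the acceptance suite.
run_psag_pipeline <- function(cfg) {
  ref <- generate_reference_atlas(cfg)
  qry <- generate_query_atlas(cfg, ref)
  ref_norm <- normalize_lognorm(ref$matrix)
  qry_norm <- normalize_lognorm(qry$matrix)

  young_old <- rank_markers(qry_norm, qry$annotation$true_bin, group_a = "young",
                            test = "wilcoxon", adjust = "bonferroni")
  set_young <- filter_degs(young_old, threshold_spec(1.5, 0.01), "up", "young_up")

  joint <- expr_matrix(cbind(qry_norm$values, ref_norm$values), layer = "lognorm")
  grp <- c(rep("tumor", ncol(qry_norm$values)), rep("normal", ncol(ref_norm$values)))
  tum_norm <- rank_markers(joint, grp, group_a = "tumor",
                           test = "wilcoxon", adjust = "bonferroni")
  set_tumor <- filter_degs(tum_norm, threshold_spec(0.5, 0.01), "up", "tumor_up")

  bulk <- expr_matrix(cbind(
    pseudo_bulk(qry$matrix, cell_ids(qry$matrix), 12, 40, "gbm", cfg$seed + 10),
    pseudo_bulk(ref$matrix, cell_ids(ref$matrix), 12, 40, "nrm", cfg$seed + 11)
  ), layer = "bulk_log2tpm")
  bulk_deg <- rank_markers(bulk, rep(c("gbm", "normal"), each = 12), group_a = "gbm",
                           test = "welch", adjust = "bh")
  set_bulk <- filter_degs(bulk_deg, threshold_spec(1.5, 0.01), "up", "bulk_up")

  map <- casing_ortholog_map(gene_programs(cfg)$genes)
  aging <- generate_aging_atlas(cfg, map)
  aging_deg <- rank_markers(normalize_lognorm(aging$matrix),
                            aging$annotation$age_label, group_a = "young",
                            test = "wilcoxon", adjust = "bh")
  set_aging <- filter_degs(aging_deg, threshold_spec(0.1, 0.05), "up", "aging_young_up")

  psag <- derive_psag(set_young, set_tumor, set_bulk, set_aging, map)
  list(psag = psag, planted = gene_programs(cfg)$anti_senescence,
       sets = list(young = set_young, tumor = set_tumor,
                   bulk = set_bulk, aging = set_aging))
}

precision_recall <- function(found, truth) {
  c(precision = if (length(found)) length(intersect(found, truth)) / length(found) else 0,
    recall = length(intersect(found, truth)) / length(truth))
}
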