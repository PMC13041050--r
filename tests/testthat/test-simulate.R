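test_that("generators are deterministic under a fixed seed", {
  cfg <- small_config()
  ref1 <- generate_reference_atlas(cfg)
  ref2 <- generate_reference_atlas(cfg)
  expect_identical(as.matrix(ref1$matrix$values), as.matrix(ref2$matrix$values))
  expect_identical(ref1$annotation, ref2$annotation)

  qry1 <- generate_query_atlas(cfg, ref1)
  qry2 <- generate_query_atlas(cfg, ref2)
  expect_identical(as.matrix(qry1$matrix$values), as.matrix(qry2$matrix$values))

  map <- casing_ortholog_map(gene_programs(cfg)$genes)
  ag1 <- generate_aging_atlas(cfg, map)
  ag2 <- generate_aging_atlas(cfg, map)
  expect_identical(as.matrix(ag1$matrix$values), as.matrix(ag2$matrix$values))

  sc <- survival_sim_config(seed = 7L)
  expect_identical(generate_survival_cohort(sc)$time,
                   generate_survival_cohort(sc)$time)
})

test_that("counts are non-negative integers and metadata aligns with cells", {
  cfg <- small_config()
  for (sim in list(generate_reference_atlas(cfg),
                   generate_query_atlas(cfg, generate_reference_atlas(cfg)))) {
    v <- sim$matrix$values
    expect_true(all(v@x >= 0) && all(v@x == round(v@x)))
    expect_identical(sim$annotation$cell_id, cell_ids(sim$matrix))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_genes = 0), "positive")
  expect_error(simulation_config(young_fraction = 1.5), "young_fraction")
  expect_error(simulation_config(n_genes = 100), "planted programs")
  expect_error(survival_sim_config(causal_genes = "GENE0001", betas = numeric()),
               "equal length")
  expect_error(survival_sim_config(censor_rate = 1), "censor_rate")
  expect_error(generate_aging_atlas(small_config(),
                                    ortholog_map(character(), character())),
               "empty")
})

test_that("age-program means are strictly graded by rank distance", {
  # oracle: group means recomputed directly from the emitted counts
  cfg <- small_config(effect_size = 1.0)
  ref <- generate_reference_atlas(cfg)
  programs <- gene_programs(cfg)
  rank_of <- match(ref$annotation$age_label, cfg$age_levels)
  counts <- as.matrix(ref$matrix$values)
  lib <- colSums(counts)
  cpm <- sweep(counts, 2, lib, "/")
  mid_levels <- seq(cfg$age_bandwidth + 1, length(cfg$age_levels) - cfg$age_bandwidth)
  for (a in mid_levels) {
    prog <- programs$age[[a]]
    mean_at_d <- vapply(0:cfg$age_bandwidth, function(d) {
      mean(cpm[prog, abs(rank_of - a) == d])
    }, numeric(1))
    expect_true(all(diff(mean_at_d) < 0),
                info = sprintf("program %s not graded", cfg$age_levels[a]))
  }
})

test_that("zero effect size removes the age gradient", {
  n_sig <- 0L
  for (s in 1:20) {
    cfg <- small_config(effect_size = 0, seed = 100L + s,
                        n_cells_per_group = 15)
    ref <- generate_reference_atlas(cfg)
    programs <- gene_programs(cfg)
    rank_of <- match(ref$annotation$age_label, cfg$age_levels)
    cpm <- sweep(as.matrix(ref$matrix$values), 2,
                 colSums(as.matrix(ref$matrix$values)), "/")
    prog <- programs$age[[1]]
    near <- colMeans(cpm[prog, rank_of == 1])
    far <- colMeans(cpm[prog, rank_of == length(cfg$age_levels)])
    if (stats::t.test(near, far)$p.value < 0.01) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 2L)  # ~0.2 expected under the null at alpha = 0.01
})

test_that("query atlas bin mixture matches young_fraction", {
  cfg <- small_config(young_fraction = 0)
  ref <- generate_reference_atlas(cfg)
  expect_true(all(generate_query_atlas(cfg, ref)$annotation$true_bin == "old"))

  cfg1 <- small_config(young_fraction = 1)
  expect_true(all(generate_query_atlas(cfg1, generate_reference_atlas(cfg1))$annotation$true_bin == "young"))

  # 99% binomial interval around 0.3 at n = 1000
  cfg3 <- simulation_config(n_genes = 600, n_cells_per_group = 500,
                            young_fraction = 0.3, seed = 5L)
  qry <- generate_query_atlas(cfg3, generate_reference_atlas(cfg3))
  phat <- mean(qry$annotation$true_bin == "young")
  half <- stats::qnorm(0.995) * sqrt(0.3 * 0.7 / 1000)
  expect_gt(phat, 0.3 - half)
  expect_lt(phat, 0.3 + half)
})

test_that("query atlas requires a compatible gene universe", {
  cfg <- small_config()
  ref <- generate_reference_atlas(cfg)
  cfg_bad <- small_config(n_genes = 700)
  expect_error(generate_query_atlas(cfg_bad, ref), "gene universe")
})

test_that("aging atlas plants recoverable young-up orthologs", {
  hits <- 0L
  n_rep <- 20L
  for (s in seq_len(n_rep)) {
    cfg <- simulation_config(n_genes = 600, n_cells_per_group = 200,
                             seed = 200L + s)
    map <- casing_ortholog_map(gene_programs(cfg)$genes)
    aging <- generate_aging_atlas(cfg, map)
    deg <- rank_markers(normalize_lognorm(aging$matrix),
                        aging$annotation$age_label, group_a = "young",
                        adjust = "bh")
    up <- filter_degs(deg, threshold_spec(0.1, 0.05), "up")
    if (all(aging$truth$young_up_orthologs %in% up$genes)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("an ortholog map covering no planted genes yields an empty signature", {
  cfg <- small_config()
  programs <- gene_programs(cfg)
  background <- setdiff(programs$genes, programs$anti_senescence)[1:50]
  map <- casing_ortholog_map(background)
  aging <- generate_aging_atlas(cfg, map)
  expect_length(aging$truth$young_up_orthologs, 0)
  candidates <- gene_set("cand", programs$anti_senescence, "planted")
  young_up <- gene_set("aging", aging$truth$young_up_orthologs, "planted")
  expect_length(cross_species_filter(candidates, young_up, map)$genes, 0)
})

test_that("survival cohort respects the proportional-hazards truth", {
  # null: univariate Cox p values uniform across genes
  null_cfg <- survival_sim_config(n_samples = 120, n_genes = 500, seed = 31L)
  coh <- generate_survival_cohort(null_cfg)
  screen <- univariate_cox_screen(coh, p_max = 0.05)
  expect_gt(stats::ks.test(screen$p_value, "punif")$p.value, 0.01)

  # coverage: fitted univariate HR CI covers the planted HR 2 in at least
  # 90% of replicates (40 replicates keep the binomial check reliable)
  covered <- 0L
  n_rep <- 40L
  for (s in seq_len(n_rep)) {
    cfg <- survival_sim_config(n_samples = 500, n_genes = 20,
                               causal_genes = "GENE0001", betas = log(2),
                               seed = 400L + s)
    coh <- generate_survival_cohort(cfg)
    x <- coh$expression["GENE0001", ]
    fit <- survival::coxph(survival::Surv(coh$time, coh$event) ~ x)
    ci <- exp(stats::confint(fit))
    if (ci[1] <= 2 && 2 <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.9)

  # censoring contract
  no_cens <- generate_survival_cohort(survival_sim_config(censor_rate = 0, seed = 2L))
  expect_true(all(no_cens$event == 1L))
  cens <- generate_survival_cohort(survival_sim_config(
    n_samples = 2000, censor_rate = 0.3, seed = 3L))
  expect_lt(abs(mean(cens$event == 0) - 0.3), 0.05)
})
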