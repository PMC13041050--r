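test_that("the selector roster enumerates exactly 18 model configurations", {
  roster <- selector_roster()
  expect_equal(nrow(roster), 18L)
  expect_equal(sum(grepl("^enet", roster$model_id)), 9L)
  expect_equal(sum(grepl("^stepcox", roster$model_id)), 3L)
  expect_true(all(c("lasso", "boruta", "coxboost", "rsf", "xgboost", "svm_rfe")
                  %in% roster$model_id))
  expect_false(anyDuplicated(roster$model_id) > 0)
})

test_that("univariate Cox screening has power and controls type I error", {
  # power: a planted log(3) effect is retained almost always
  hits <- 0L
  for (s in 1:20) {
    cfg <- survival_sim_config(n_samples = 300, n_genes = 10,
                               causal_genes = "GENE0001", betas = log(3),
                               seed = 500L + s)
    screen <- univariate_cox_screen(generate_survival_cohort(cfg), p_max = 0.05)
    if (screen$retained[screen$gene == "GENE0001"]) hits <- hits + 1L
  }
  expect_gte(hits, 19L)

  # type I: pure-noise retention within the 99% binomial interval of p_max
  null_coh <- generate_survival_cohort(
    survival_sim_config(n_samples = 150, n_genes = 500, seed = 77L))
  screen <- univariate_cox_screen(null_coh, p_max = 0.05)
  phat <- mean(screen$retained)
  half <- stats::qnorm(0.995) * sqrt(0.05 * 0.95 / 500)
  expect_gt(phat, 0.05 - half)
  expect_lt(phat, 0.05 + half)

  # constant genes are skipped, the run completes
  coh <- generate_survival_cohort(survival_sim_config(n_samples = 50, n_genes = 10, seed = 3L))
  coh$expression["GENE0002", ] <- 1
  expect_message(out <- univariate_cox_screen(coh), "constant")
  expect_false("GENE0002" %in% out$gene)

  expect_error(univariate_cox_screen(
    generate_survival_cohort(survival_sim_config(n_samples = 10, seed = 1L))),
    "at least 20")
})

test_that("repeated Lasso counts behave at n_runs = 1", {
  cfg <- survival_sim_config(n_samples = 100, n_genes = 10,
                             causal_genes = "GENE0001", betas = log(3), seed = 9L)
  coh <- generate_survival_cohort(cfg)
  out <- repeated_lasso_select(coh, rownames(coh$expression),
                               n_runs = 1, min_count = 1, seed = 4L)
  expect_true(all(out$counts$count %in% 0:1))
  expect_length(out$retained, 0)  # count can never exceed min_count = 1
})

test_that("stability selection retains planted genes and rejects noise", {
  planted <- c("GENE0001", "GENE0002", "GENE0003")
  for (s in 1:2) {
    cfg <- survival_sim_config(n_samples = 400, n_genes = 53,
                               causal_genes = planted, betas = rep(log(2.5), 3),
                               seed = 600L + s)
    coh <- generate_survival_cohort(cfg)
    out <- repeated_lasso_select(coh, rownames(coh$expression),
                                 n_runs = 30, min_count = 5, seed = 10L + s)
    expect_true(all(planted %in% out$retained))
    expect_lte(length(setdiff(out$retained, planted)), 2L)
    # monotone stability: planted counts dominate noise counts
    cnt <- setNames(out$counts$count, out$counts$gene)
    expect_gt(min(cnt[planted]), max(0, mean(cnt[setdiff(names(cnt), planted)])))
  }
})

test_that("frequency aggregation matches hand tabulation and ignores cohort order", {
  # 4 genes x 3 models x 2 cohorts indicator tensor, tabulated by hand
  grid <- tidyr::expand_grid(gene = c("g1", "g2", "g3", "g4"),
                             model_id = c("m1", "m2", "m3"),
                             cohort = c("c1", "c2"))
  grid$selected <- as.integer(
    (grid$gene == "g1") |                       # g1: all models, both cohorts -> 3
    (grid$gene == "g2" & grid$model_id == "m1") | # g2: 1 model each cohort -> 1
    (grid$gene == "g3" & grid$cohort == "c1"))    # g3: 3 in c1, 0 in c2 -> 1.5
  ft <- aggregate_frequency(grid)
  expect_equal(ft$average_frequency[match(c("g1", "g2", "g3", "g4"), ft$gene)],
               c(3, 1, 1.5, 0))
  expect_equal(ft$freq_c1[match("g3", ft$gene)], 3)
  expect_equal(ft$freq_c2[match("g3", ft$gene)], 0)
  expect_identical(ft$gene[ft$rank == 1], "g1")
  expect_identical(sort(ft$rank), 1:4)

  # invariant to cohort ordering
  ft2 <- aggregate_frequency(dplyr::arrange(grid, dplyr::desc(cohort), gene))
  expect_equal(ft2$average_frequency[match(ft$gene, ft2$gene)], ft$average_frequency)

  # a gene picked by 3 of the models in every cohort averages 3
  expect_equal(ft$average_frequency[ft$gene == "g1"], 3)

  # sum summary is the across-cohort total
  fts <- aggregate_frequency(grid, summary = "sum")
  expect_equal(fts$average_frequency[fts$gene == "g1"], 6)
})

test_that("the selector roster runs end to end and votes for planted genes", {
  planted <- c("GENE0001", "GENE0002")
  cfg <- survival_sim_config(n_samples = 150, n_genes = 20,
                             causal_genes = planted, betas = rep(log(2.5), 2),
                             seed = 21L)
  cohorts <- list(c1 = generate_survival_cohort(cfg))
  config <- selection_config(n_lasso_runs = 10, lasso_min_count = 2, nfolds = 5)
  ind <- run_selector_roster(cohorts, rownames(cohorts$c1$expression),
                             config = config, seed = 2L)
  ran <- unique(ind$model_id)
  expect_true(all(c("lasso", "enet_0.5", "stepcox_forward", "rsf", "xgboost") %in% ran))
  expect_false(any(c("boruta", "coxboost", "svm_rfe") %in% ran))
  ft <- aggregate_frequency(ind)
  expect_true(all(match(planted, ft$gene[order(ft$rank)]) <= 5))

  # a custom implementation plugs into the roster
  ind2 <- run_selector_roster(cohorts, rownames(cohorts$c1$expression),
                              config = config, seed = 2L,
                              impls = list(boruta = function(cohort, genes, seed) genes[1]))
  expect_true("boruta" %in% ind2$model_id)
})

test_that("median-split survival recovers planted hazards", {
  # null split: duplicated outcomes give HR near 1 and large p
  cfg0 <- survival_sim_config(n_samples = 200, n_genes = 5, seed = 12L)
  coh0 <- generate_survival_cohort(cfg0)
  res0 <- median_split_logrank(coh0, "GENE0001")
  expect_gt(res0$logrank_p, 0.05)

  # planted HR = 2 on a bimodal gene: CI covers 2
  cfg <- survival_sim_config(n_samples = 500, n_genes = 10,
                             causal_genes = "GENE0001", betas = log(2), seed = 13L)
  coh <- generate_survival_cohort(cfg)
  res <- median_split_logrank(coh, "GENE0001")
  expect_lt(res$ci_lower, 2)
  expect_gt(res$ci_upper, 2)
  expect_lt(res$logrank_p, 0.01)

  # tie rule: odd n puts ceiling(n/2) samples in the low stratum
  odd <- generate_survival_cohort(survival_sim_config(n_samples = 101, n_genes = 5, seed = 14L))
  ro <- median_split_logrank(odd, "GENE0002")
  expect_equal(ro$n_low, 51L)

  # scale equivariance: rescaling expression leaves the split unchanged
  coh2 <- coh
  coh2$expression["GENE0001", ] <- coh$expression["GENE0001", ] * 7.5
  res2 <- median_split_logrank(coh2, "GENE0001")
  expect_equal(res2$logrank_p, res$logrank_p)
  expect_equal(res2$hr, res$hr)

  flat <- coh
  flat$expression["GENE0003", ] <- 2
  expect_error(median_split_logrank(flat, "GENE0003"), "Zero-variance")
})

test_that("multivariate Cox adjusts for covariates and flags collinearity", {
  # joint recovery of two independent planted effects
  cfg <- survival_sim_config(n_samples = 600, n_genes = 10,
                             causal_genes = c("GENE0001", "GENE0002"),
                             betas = c(log(2), log(1.5)), seed = 15L)
  coh <- generate_survival_cohort(cfg)
  res <- multivariate_cox(coh, "GENE0001",
                          covariates = tibble::tibble(cov = coh$expression["GENE0002", ]))
  g <- res[res$term == "GENE0001", ]
  cv <- res[res$term == "cov", ]
  expect_true(g$ci_lower < 2 && 2 < g$ci_upper)
  expect_true(cv$ci_lower < 1.5 && 1.5 < cv$ci_upper)

  # a covariate identical to the gene is a collinearity error
  expect_error(
    multivariate_cox(coh, "GENE0001",
                     covariates = tibble::tibble(dup = coh$expression["GENE0001", ])),
    "Collinear")

  # null gene with a strong covariate: gene CI covers 1 in most replicates
  covered <- 0L
  for (s in 1:20) {
    cfgn <- survival_sim_config(n_samples = 300, n_genes = 10,
                                causal_genes = "GENE0002", betas = log(2.5),
                                seed = 700L + s)
    cohn <- generate_survival_cohort(cfgn)
    rn <- multivariate_cox(cohn, "GENE0001",
                           covariates = tibble::tibble(cov = cohn$expression["GENE0002", ]))
    gi <- rn[rn$term == "GENE0001", ]
    if (gi$ci_lower <= 1 && 1 <= gi$ci_upper) covered <- covered + 1L
  }
  expect_gte(covered, 18L)
})

test_that("cohort round-trips through the TSV form", {
  dir <- withr::local_tempdir()
  cfg <- survival_sim_config(n_samples = 30, n_genes = 8, seed = 16L)
  coh <- generate_survival_cohort(cfg)
  path <- file.path(dir, "cohort.tsv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$expression, coh$expression)
  expect_equal(back$time, coh$time)
  expect_equal(back$event, coh$event)
})
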