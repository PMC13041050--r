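# Shared scaled-down atlas used across projection tests.
projection_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_config(n_cells_per_group = 30)
      ref <- generate_reference_atlas(cfg)
      norm <- normalize_lognorm(ref$matrix)
      hvg <- suppressWarnings(select_hvg(norm, 500))
      emb <- pca_embed(norm, hvg, n_pcs = 15)
      cache <<- list(cfg = cfg, ref = ref, norm = norm, emb = emb)
    }
    cache
  }
})

test_that("query projection matches the closed form and self-projects exactly", {
  fx <- projection_fixture()
  qemb <- project_query(fx$emb, fx$norm)
  expect_lt(max(abs(qemb - fx$emb$embedding)), 1e-9)

  # closed-form oracle on a 5-gene toy: (x - mean) %*% loadings
  withr::with_seed(11, {
    m <- toy_matrix(matrix(abs(rnorm(5 * 8)), 5, 8))
  })
  emb <- pca_embed(m, gene_ids(m), n_pcs = 2)
  q <- toy_matrix(matrix(c(0.3, 1.2, 0.1, 0.8, 2.0), 5, 1), cells = "q1")
  by_hand <- (as.numeric(q$values) - emb$gene_means) %*% emb$loadings
  expect_equal(as.numeric(suppressWarnings(project_query(emb, q))),
               as.numeric(by_hand), tolerance = 1e-12)

  # a query equal to a reference profile lands on that cell
  q2 <- toy_matrix(as.matrix(m$values[, 3, drop = FALSE]), cells = "copy")
  expect_lt(max(abs(suppressWarnings(project_query(emb, q2)) - emb$embedding[3, ])),
            1e-9)

  # disjoint gene universe errors
  q3 <- toy_matrix(matrix(1, 2, 1), genes = c("zz1", "zz2"))
  expect_error(project_query(emb, q3), "shared genes")
})

test_that("identical point clouds anchor every cell to its copy with score 1", {
  withr::with_seed(2, {
    pts <- matrix(rnorm(40), 20, 2, dimnames = list(sprintf("r%d", 1:20), NULL))
  })
  qry <- pts
  rownames(qry) <- sprintf("q%d", 1:20)
  anch <- find_anchors(pts, qry, k_anchor = 3, k_score = 10)
  is_self <- sub("q", "r", anch$query_cell) == anch$ref_cell
  # every cell is anchored to its copy, and those anchors score 1
  expect_setequal(anch$ref_cell[is_self], rownames(pts))
  expect_true(all(anch$score[is_self] == 1))
})

test_that("anchors never cross well-separated clusters", {
  withr::with_seed(3, {
    mk <- function(center, n, prefix) {
      m <- matrix(rnorm(n * 2, sd = 0.3), n, 2)
      m <- sweep(m, 2, center, "+")
      rownames(m) <- sprintf("%s%d", prefix, seq_len(n))
      m
    }
    ref <- rbind(mk(c(0, 0), 25, "ra"), mk(c(20, 20), 25, "rb"))
    qry <- rbind(mk(c(0, 0), 25, "qa"), mk(c(20, 20), 25, "qb"))
  })
  anch <- find_anchors(ref, qry, k_anchor = 5, k_score = 10)
  ref_cluster <- substr(anch$ref_cell, 2, 2)
  qry_cluster <- substr(anch$query_cell, 2, 2)
  expect_true(all(ref_cluster == qry_cluster))
  # brute-force oracle: exhaustive nearest-neighbor enumeration agrees
  d <- as.matrix(stats::dist(rbind(ref, qry)))[1:50, 51:100]
  for (i in seq_len(nrow(anch))) {
    r <- anch$ref_cell[i]; q <- anch$query_cell[i]
    expect_lte(rank(d[r, ])[q], 5)
    expect_lte(rank(d[, q])[r], 5)
  }
})

test_that("k_anchor = 1 on a 3-point toy finds the single mutual pair", {
  ref <- matrix(c(0, 0, 10, 0, 20, 0), 3, 2, byrow = TRUE,
                dimnames = list(c("r1", "r2", "r3"), NULL))
  qry <- matrix(c(1, 0, 14, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("q1", "q2"), NULL))
  # by hand: r1<->q1 (1 apart) and r2<->q2 (4 apart) are mutual nearest
  # neighbors; r3's nearest query is q2 but q2's nearest reference is r2,
  # so r3 is unanchored.
  anch <- find_anchors(ref, qry, k_anchor = 1, k_score = 2)
  expect_identical(sort(paste(anch$ref_cell, anch$query_cell)),
                   c("r1 q1", "r2 q2"))
})

test_that("label transfer votes, scores and handles degenerate anchors", {
  fx <- projection_fixture()
  qemb <- project_query(fx$emb, fx$norm)
  anch <- find_anchors(fx$emb, qemb)
  res <- transfer_labels(anch, fx$ref$annotation, qemb)

  # probability-derived scores are valid probabilities
  expect_true(all(res$transfer_score >= 0 & res$transfer_score <= 1 + 1e-9))
  expect_true(all(res$cell_type_score >= 0 & res$cell_type_score <= 1 + 1e-9))

  # self-mapping recovers the annotation almost perfectly at small scale
  expect_gte(mean(res$projected_cell_type == fx$ref$annotation$cell_type), 0.99)
  expect_gte(mean(res$projected_age == fx$ref$annotation$age_label), 0.9)

  # single-label anchors give that label with score 1
  ann1 <- fx$ref$annotation
  ann1$age_label <- "GW9"
  ann1$cell_type <- "astrocyte"
  res1 <- transfer_labels(anch, ann1, qemb)
  expect_true(all(res1$projected_age == "GW9"))
  expect_equal(res1$transfer_score, rep(1, nrow(res1)), tolerance = 1e-9)

  # order invariance: permuting query cells permutes results identically
  perm <- withr::with_seed(8, sample(nrow(qemb)))
  res_perm <- transfer_labels(anch, fx$ref$annotation, qemb[perm, ])
  expect_identical(res_perm$projected_age,
                   res$projected_age[match(res_perm$cell_id, res$cell_id)])

  expect_error(transfer_labels(anch[0, ], fx$ref$annotation, qemb), "Empty anchor")
})

test_that("young/old binning follows the gestational-week rule", {
  levels <- c("GW7", "GW9", "GW11", "GW14", "GW16", "GW20", "GW28")
  rule <- age_bin_rule(levels)
  res <- structure(
    tibble::tibble(cell_id = c("a", "b", "c", "d"),
                   projected_cell_type = "x", cell_type_score = 1,
                   projected_age = c("GW9", "GW16", "GW14", "unassigned"),
                   transfer_score = c(1, 1, 1, 0), tie_flag = FALSE),
    class = c("projection_result", class(tibble::tibble())))
  binned <- bin_projected_age(res, rule)
  expect_identical(binned$age_bin, c("young", "old", "young", NA))

  bad <- res
  bad$projected_age[1] <- "GW99"
  expect_error(bin_projected_age(bad, rule), "outside the reference")
  expect_error(age_bin_rule(levels, young_set = "GW5"), "subset")
})

test_that("bin recovery improves monotonically with the planted effect size", {
  acc <- vapply(c(0.5, 1.0, 2.0), function(es) {
    cfg <- simulation_config(n_genes = 600, n_cells_per_group = 30,
                             effect_size = es, seed = 21L)
    ref <- generate_reference_atlas(cfg)
    qry <- generate_query_atlas(cfg, ref)
    norm <- normalize_lognorm(ref$matrix)
    emb <- pca_embed(norm, suppressWarnings(select_hvg(norm, 500)), 15)
    qe <- project_query(emb, normalize_lognorm(qry$matrix))
    res <- bin_projected_age(
      transfer_labels(find_anchors(emb, qe), ref$annotation, qe),
      age_bin_rule(cfg$age_levels))
    mean(res$age_bin == qry$annotation$true_bin)
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_gte(acc[2], 0.9)
})
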