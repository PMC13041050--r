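# projage

Glioma cells echo brain development: some tumor cells transcriptionally
resemble early-embryonic progenitors while others resemble later stages.
`projage` turns that observation into a measurable quantity — a
**projected developmental age** per tumor cell — and builds a complete,
testable pipeline around it for people analyzing glioma (or other
tumor/reference) single-cell and bulk transcriptomes:

* **Reference mapping.** Query cells are placed in the principal-component
  space of an age-labeled developmental reference, anchored to mutual
  nearest reference neighbors (anchors scored by shared-neighbor
  consistency), and labeled by weighted anchor voting. Transferred
  gestational-week labels are binned: GW7–GW14 → *relatively young*,
  GW16–GW28 → *relatively old*.
* **Signature derivation.** Genes upregulated in projected-young tumor
  cells (log2FC > 1.5, adjusted p < 0.01), in tumor versus normal cells
  (log2FC > 0.5, p < 0.01) and in bulk tumor versus normal tissue are
  intersected, then filtered to genes whose ortholog is young-upregulated
  in a brain-aging atlas (log2FC > 0.1, p < 0.05) — a projected
  senescence-associated gene signature.
* **Prognostic feature selection.** An 18-model frequency-voting ensemble
  (Lasso stability selection with 1,000 reseeded runs and a >50-count
  retention rule; elastic nets at α = 0.1–0.9; stepwise Cox ×3; random
  survival forest; gradient boosting; pluggable Boruta/CoxBoost/SVM-RFE)
  ranks genes by how many models and cohorts select them.
* **Meta-programs.** Per-sample non-negative matrix factorization and
  cosine-similarity consensus recover shared tumor-cell expression
  programs, with per-gene explanatory power and confidence scores.
* **Scoring.** Bin-controlled module scores, single-sample GSEA
  (rank-weighted running sum, exponent 0.25), 0–1 rescaling, composite
  ratios (M1/M2 macrophage polarization, pro-/anti-tumor cytokines),
  gene-pair means, gene-positive fractions, and median-split /
  multivariate Cox survival analysis.

Every stage is exercisable without external downloads through seeded
synthetic-data generators with planted ground truth
(`generate_reference_atlas()`, `generate_query_atlas()`,
`generate_aging_atlas()`, `generate_survival_cohort()`,
`generate_program_atlas()`).

## Worked example

Project a synthetic tumor atlas onto its development reference and
recover the hidden young/old bins:

```r
library(projage)

cfg <- simulation_config(n_genes = 600, n_cells_per_group = 60, seed = 1)
ref <- generate_reference_atlas(cfg)
qry <- generate_query_atlas(cfg, ref)

ref_norm <- normalize_lognorm(ref$matrix)
emb <- pca_embed(ref_norm, select_hvg(ref_norm, 500), n_pcs = 15)
q_emb <- project_query(emb, normalize_lognorm(qry$matrix))
anchors <- find_anchors(emb, q_emb)
result <- transfer_labels(anchors, ref$annotation, q_emb) |>
  bin_projected_age(age_bin_rule(cfg$age_levels))

result
#> # A tibble: 120 × 7
#>    cell_id  projected_cell_type cell_type_score projected_age transfer_score
#>    <chr>    <chr>                         <dbl> <chr>                  <dbl>
#>  1 tum_0001 oligodendrocyte               1     GW20                   0.989
#>  2 tum_0002 astrocyte                     1     GW9                    0.983
#>  3 tum_0003 astrocyte                     1.000 GW14                   0.779
#>  4 tum_0004 astrocyte                     1     GW11                   0.997
#>  5 tum_0005 astrocyte                     1     GW7                    0.991
#> # ℹ 115 more rows, 2 more variables: tie_flag <lgl>, age_bin <chr>

glance(result)
#> # A tibble: 1 × 4
#>   n_cells n_unassigned mean_transfer_score frac_young
#>     <int>        <int>               <dbl>      <dbl>
#> 1     120            0               0.937      0.475

mean(result$age_bin == qry$annotation$true_bin)
#> [1] 1
```

Each row is one tumor cell: `projected_age` is the gestational-week label
transferred from its reference anchors, `transfer_score` the winning
label's vote share (a probability), and `age_bin` the young/old call. Here
all 120 hidden bins are recovered; `frac_young` ≈ 0.475 matches the
planted mixture. From here, `rank_markers()` + `filter_degs()` +
`derive_psag()` derive the signature, and `run_selector_roster()` +
`aggregate_frequency()` rank its genes by prognostic selection frequency
(`autoplot()` draws the lollipop chart).

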