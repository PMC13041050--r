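---
title: "Projected developmental age mapping and senescence signature discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projected developmental age mapping and senescence signature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Gliomas contain tumor cells whose transcriptomes resemble cells from
different stages of brain development. `projage` quantifies that
resemblance by *reference mapping*: tumor cells are projected into the
principal-component space of an age-labeled developmental reference atlas,
anchored to their mutual nearest reference neighbors, and assigned a
"projected age" — the gestational-week (GW) label carried over from their
anchors. Labels GW7–GW14 (early-embryonic) define *relatively young* tumor
cells; GW16 onward (mid-embryonic) defines *relatively old* cells. The
working hypothesis is that projected-young tumor cells are the ones most
actively antagonizing senescence, so genes upregulated in them — and also
upregulated in tumor versus normal tissue, and in young versus aged brain
of another species — form a projected senescence-associated signature.

The pipeline has five computational stages, each exposed as ordinary
functions over sparse matrices and tibbles:

1. **Preprocessing** (`qc_filter()`, `normalize_lognorm()`,
   `select_hvg()`, `pca_embed()`): cells with fewer than 500 or more than
   7,500 detected genes, or more than 10% mitochondrial counts, are
   removed (the boundary values themselves are retained — the removal
   inequalities are strict); counts are library-size log-normalized
   (`ln(1 + count/total * 1e4)`); the 3,000 most variable genes are
   embedded on 15 principal components after per-gene centering, without
   unit-variance scaling. No batch correction is performed.
2. **Projection** (`project_query()`, `find_anchors()`,
   `transfer_labels()`, `bin_projected_age()`): the query is centered
   with the *reference* gene means and rotated by the reference loadings;
   anchors are mutual `k_anchor = 5` nearest neighbors scored by the
   overlap of their `k_score = 30` pooled neighborhoods
   (quantile-rescaled to [0, 1]); each query cell's `k_weight = 50`
   nearest anchors vote for its cell type and age label with
   Gaussian-kernel, score-multiplied weights normalized to sum one.
3. **Signature derivation** (`rank_markers()`, `filter_degs()`,
   `derive_psag()`): Wilcoxon (single cell) or Welch (bulk) tests with
   the stage-specific strict thresholds — log2 fold change above 1.5 and
   adjusted p below 0.01 for young-vs-old tumor cells, 0.5/0.01 for tumor
   versus normal cells, 1.5/0.01 for bulk tumor versus normal tissue, and
   0.1/0.05 for the cross-species aging contrast — followed by exact
   three-way intersection and an ortholog-mediated filter that keeps
   candidates with at least one young-upregulated ortholog.
4. **Prognostic feature selection** (`univariate_cox_screen()`,
   `repeated_lasso_select()`, `run_selector_roster()`,
   `aggregate_frequency()`): a univariate proportional-hazards prefilter,
   then an 18-model ensemble — Lasso, nine elastic nets (alpha 0.1–0.9),
   three stepwise-Cox directions, and five pluggable selectors (random
   survival forest and gradient boosting ship with implementations;
   Boruta, CoxBoost and SVM-RFE accept user implementations). The Lasso
   entry is stability selection: 1,000 penalized fits whose
   cross-validation folds are reseeded each run, a gene being retained
   when selected in strictly more than 50 runs. Gene votes are averaged
   across cohorts and ranked.
5. **Meta-programs and scoring** (`nmf_programs_per_sample()`,
   `consensus_metaprograms()`, `module_score()`, `ssgsea()`): per-sample
   non-negative matrix factorization at ranks 4–6, consensus clustering
   of programs by cosine similarity, and per-cell/per-sample gene-set
   scores with 0–1 rescaling and composite ratios (M1/M2 polarization,
   pro-/anti-tumor cytokines).

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_genes`, `max_genes` | 500, 7500 | detected-gene retention bounds (inclusive) |
| `max_mito` | 0.10 | maximum mitochondrial count fraction |
| `n_hvg`, `n_pcs` | 3000, 15 | embedding dimensionality |
| `k_anchor`, `k_score`, `k_weight` | 5, 30, 50 | anchor mutuality, scoring and voting neighborhoods |
| young set | GW7–GW14 | early-embryonic bin (GW14 inclusive) |
| DEG thresholds | stage-specific | strict `log2FC >` and `p_adj <` cutoffs listed above |
| `n_lasso_runs`, `lasso_min_count` | 1000, 50 | stability-selection runs and retention count |
| `k_values`, `cosine_min`, `min_genes` (MP) | 4–6, 0.7, 10 | NMF ranks, merge threshold, strict size floor |
| power / confidence minima | 0.5, 0.7 | strict meta-program gene retention thresholds |
| `n_bins`, `n_ctrl` | 24, 100 | module-score control bins and controls per gene |
| ssGSEA `alpha` | 0.25 | rank-weight exponent |

The anchor-transfer neighborhood sizes are conventional reference-mapping
defaults; no sizes are canonical for the KNN, MNN and SNN steps, so all
three are exposed in the API. The
module-score bin/control counts follow the convention of the widely used
implementation of that score. The voting kernel uses an adaptive
bandwidth of **one third** of the distance to the `k_weight`-th anchor:
with the bandwidth equal to that distance the kernel still has weight
`exp(-1)` at the edge of the neighborhood, votes blur across adjacent
age levels, and reference self-mapping accuracy drops measurably; at a
third, the kernel has effectively vanished (about `1e-4`) at the edge
while remaining smooth near the cell.

## The synthetic-data generators

No public generative model exists for these data, so the package ships
seeded generators with planted ground truth:

* **Reference atlas** — negative-binomial counts whose log-mean is a
  shared per-gene baseline plus additive programs: one per cell type, one
  per age level, each of 30 genes with a mean log-fold shift of 1.0
  (natural log). An age program peaks at its own level and decays
  linearly with rank distance, vanishing beyond `age_bandwidth = 2`
  ranks. A transient, bandwidth-limited profile was chosen over a ramp
  spanning the whole axis: developmental stage programs are expressed
  around their stage, not across the entire 21-week span, and a full-span
  ramp makes adjacent levels transcriptionally near-indistinguishable
  (self-mapping accuracy collapses to ~0.55, i.e. "projected age" stops
  being well-posed). Defaults: 2,000 genes, 200 cells per age level,
  eleven levels GW7–GW28, library size log-normal around 5,000,
  dispersion 0.3.
* **Query atlas** — a young/old mixture (default 50/50, 400 cells) whose
  cells sample young (GW7–14) or old (GW16+) age programs, plus a
  malignancy program active in every tumor cell and an anti-senescence
  program active in every tumor cell (0.75x effect) and more strongly in
  young-bin cells (+1.5x). The anti-senescence program is the planted
  truth the signature derivation must recover.
* **Aging atlas** — young and old cells in an orthologous gene namespace
  (default map: upper-case human symbol to capitalized ortholog), with
  the mapped anti-senescence orthologs upregulated in young cells.
* **Survival cohorts** — exponential-baseline proportional hazards with
  linear predictor `sum(beta_g * expr_g)`. Causal genes are emitted as
  on/off bimodal expression (Bernoulli 0/1 plus 0.05-SD jitter),
  emulating expression-subtype markers, so the planted `exp(beta)` is
  also the high-versus-low hazard ratio at a median split; noise genes
  are standard normal. Censoring is independent exponential with its
  rate solved (by `uniroot` on `mean(r/(r+h_i))`) so the expected
  censored fraction equals the configured rate.
* **Program atlas** — multi-sample pseudo-tumors in which each cell
  activates one of several shared 30-gene programs (log-mean shift 2),
  the fixture for meta-program consensus.

What the generators deliberately do **not** emulate: doublets, ambient
RNA, batch effects, spatial structure, gene length variation, and
realistic gene-gene correlation beyond the planted programs. Tests
passing on these data therefore demonstrate the *procedures* are
implemented correctly and recover planted truth under idealized noise;
they say nothing about robustness to batch structure or to reference
atlases whose stages are intrinsically continuous.

## Numerical choices

* **Fold changes**: for log-normalized data,
  `log2((mean(expm1 A) + 1) / (mean(expm1 B) + 1))` (pseudocount one,
  back-transformed means); for bulk log2 data, the difference of group
  means. All threshold inequalities are strict.
* **Wilcoxon p values** come from `stats::wilcox.test` (exact for small
  untied samples, normal approximation otherwise); moderated bulk
  statistics (limma/DESeq2-style shrinkage) are intentionally not
  reproduced — Welch's t is the bulk surrogate, which will differ from
  moderated results most at small sample sizes.
* **Penalized Cox runs** select the support at `lambda.1se`, the largest
  penalty within one standard error of the cross-validation optimum.
  At `lambda.min` essentially every run also carries noise genes and
  count-based stability selection degenerates.
* **Stepwise Cox** uses AIC in both directions from the null (forward)
  or full (backward/both) model.
* **NMF** is multiplicative-update (Frobenius), five seeded restarts,
  tolerance `1e-6`, at most 500 iterations, best loss kept. Input is
  per-gene centered within sample and clipped at zero so factors model
  above-average expression; program similarity and consensus use
  top-50-gene truncated weight vectors — without centering and
  truncation the shared baseline component dominates every cosine and
  all programs merge.
* **Explanatory power** of a meta-program gene is its mean relative
  weight (weight over program maximum) across member programs;
  **confidence** is the fraction of member programs where the relative
  weight exceeds 0.25. Both formulas are this package's explicit
  reconstructions; the thresholds (0.5 and 0.7, strict) are exposed.
* **Median splits** send values equal to the median to the low stratum
  (odd cohorts put `ceiling(n/2)` samples in the low group).
* **Ties** in label votes are broken lexicographically and flagged;
  selection-frequency rank ties are broken by gene label and flagged.
* **scale01** maps constant input to all zeros.
* Query cells with no reachable anchor are labeled `"unassigned"` with
  transfer score 0 and a missing age bin.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at the
generator defaults (2,000 genes; 2,200 reference plus 400 query cells;
2 x 200-cell aging atlas; survival cohorts of 400–600 samples with 100
stability-selection runs and retention count 5; six 120-cell samples for
meta-programs). Unit tests use smaller versions of the same
configurations (600 genes, 30–60 cells per group) chosen so each planted
effect is still comfortably recoverable.

## Known limitations

* The shared embedding is the reference PCA space; a joint
  canonical-correlation space (as some anchor implementations use) could
  behave differently on strongly divergent queries.
* Age is transferred as a categorical label and then binned; no
  continuous pseudo-age is regressed.
* The default human–mouse ortholog map is a casing convention intended
  for synthetic symbols; real analyses should supply a curated homology
  table (`read_ortholog_map()`).
* Boruta, CoxBoost and SVM-RFE selectors are interface stubs pending an
  implementation supplied through `run_selector_roster(impls = ...)`;
  frequency aggregation is defined over the models that ran.
* The pro-/anti-tumor cytokine and M1/M2 member lists are inputs, not
  package curation.
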