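#' Simulation configuration for synthetic atlases
#'
#' Defines the generative model shared by the reference, query and aging
#' atlas generators: a negative-binomial count model whose log-mean is a
#' gene baseline plus additive program shifts (cell-type program, age-graded
#' program, malignancy program, anti-senescence program).
#'
#' Age grading: each age level owns a disjoint gene program; for a cell at
#' age rank `r` the program of the level at rank `r_a` contributes a
#' log-mean shift `effect_size * max(0, 1 - |r - r_a| / age_bandwidth)`,
#' i.e. expression peaks at the program's own level and decays linearly
#' with rank distance, vanishing beyond `age_bandwidth` ranks. Stage
#' programs are therefore transient (as developmental programs are) and
#' group means are strictly graded with rank distance inside the
#' bandwidth, which keeps "projected age" well-posed and adjacent stages
#' distinguishable.
#'
#' @param n_genes number of genes in the universe.
#' @param n_cells_per_group cells per age level (reference) or per
#'   young/old bin (query).
#' @param age_levels ordered gestational-week labels; the first levels up to
#'   and including `"GW14"` are the developmentally young bin.
#' @param cell_types cell-type labels for the reference.
#' @param program_size genes per planted program.
#' @param effect_size mean log-fold shift (natural-log scale) of program
#'   genes.
#' @param age_bandwidth rank distance at which an age program's
#'   contribution reaches zero.
#' @param library_size_mean,library_size_sdlog log-normal library-size
#'   parameters.
#' @param dispersion negative-binomial dispersion phi (variance
#'   `mu + phi * mu^2`).
#' @param young_fraction fraction of query cells drawn from young-age
#'   programs.
#' @param seed integer RNG seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_cells_per_group = 200,
                              age_levels = c("GW7", "GW9", "GW11", "GW14",
                                             "GW16", "GW18", "GW20", "GW22",
                                             "GW24", "GW26", "GW28"),
                              cell_types = c("astrocyte", "oligodendrocyte", "neuron"),
                              program_size = 30,
                              effect_size = 1.0,
                              age_bandwidth = 2,
                              library_size_mean = 5000,
                              library_size_sdlog = 0.25,
                              dispersion = 0.3,
                              young_fraction = 0.5,
                              seed = 1L) {
  if (n_genes < 1 || n_cells_per_group < 1 || program_size < 1) {
    abort("Counts in the simulation config must be positive.")
  }
  if (!length(age_levels)) abort("`age_levels` must be nonempty.")
  if (young_fraction < 0 || young_fraction > 1) {
    abort("`young_fraction` must lie in [0, 1].")
  }
  needed <- (length(cell_types) + length(age_levels) + 2) * program_size
  if (n_genes < needed) {
    abort(sprintf("Need at least %d genes for the planted programs; got %d.",
                  needed, n_genes))
  }
  structure(list(
    n_genes = as.integer(n_genes),
    n_cells_per_group = as.integer(n_cells_per_group),
    age_levels = as.character(age_levels),
    cell_types = as.character(cell_types),
    program_size = as.integer(program_size),
    effect_size = effect_size,
    age_bandwidth = age_bandwidth,
    library_size_mean = library_size_mean,
    library_size_sdlog = library_size_sdlog,
    dispersion = dispersion,
    young_fraction = young_fraction,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Deterministic planted-program layout of a simulation config
#'
#' The gene universe is carved, in order, into one program per cell type,
#' one per age level, a malignancy program (up in all tumor cells) and an
#' anti-senescence program (up in all tumor cells and further up in
#' young-bin tumor cells); remaining genes are background. The layout
#' depends only on the config, so every generator (and every test oracle)
#' can recompute it.
#'
#' @param config a [simulation_config()].
#' @return a list with `genes` (universe) and one character vector per
#'   program: `type$<cell_type>`, `age$<level>`, `malignancy`,
#'   `anti_senescence`.
#' @export
gene_programs <- function(config) {
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  k <- config$program_size
  cursor <- 0L
  take <- function() {
    out <- genes[(cursor + 1L):(cursor + k)]
    cursor <<- cursor + k
    out
  }
  type <- setNames(lapply(config$cell_types, function(.) take()), config$cell_types)
  age <- setNames(lapply(config$age_levels, function(.) take()), config$age_levels)
  list(genes = genes, type = type, age = age,
       malignancy = take(), anti_senescence = take())
}

#' Young side of the gestational-week partition
#'
#' Age levels up to and including GW14 are the early-embryonic ("young")
#' bin; GW16 onward is the mid-embryonic ("old") bin.
#'
#' @param age_levels ordered gestational-week labels.
#' @return character vector of young labels.
#' @export
young_age_levels <- function(age_levels) {
  weeks <- as.numeric(sub("^GW", "", age_levels))
  if (anyNA(weeks)) abort("Age labels must look like 'GW<week>'.")
  age_levels[weeks <= 14]
}

# Run code with a local, restored RNG state.
local_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Per-gene baseline log abundance. A property of the gene universe: the
# same config yields the same baseline in every atlas generated from it,
# so cross-atlas contrasts (tumor vs normal) see only planted shifts.
gene_baseline <- function(config, n_genes = config$n_genes) {
  local_rng(config$seed + 9000L, rnorm(n_genes, mean = 0, sd = 0.5))
}

# Negative-binomial counts from a genes x cells log-mean shift matrix.
simulate_counts <- function(config, shifts, cell_ids) {
  n_cells <- ncol(shifts)
  baseline <- gene_baseline(config)
  w <- exp(baseline + shifts)
  p <- sweep(w, 2, colSums(w), "/")
  lib <- rlnorm(n_cells, meanlog = log(config$library_size_mean),
                sdlog = config$library_size_sdlog)
  mu <- sweep(p, 2, lib, "*")
  counts <- matrix(
    rnbinom(length(mu), mu = as.vector(mu), size = 1 / config$dispersion),
    nrow = config$n_genes,
    dimnames = list(sprintf("GENE%04d", seq_len(config$n_genes)), cell_ids)
  )
  expr_matrix(counts, layer = "raw_counts")
}

# Age-program shift matrix for cells with given age ranks.
age_shift_matrix <- function(config, programs, age_rank) {
  A <- length(config$age_levels)
  shifts <- matrix(0, config$n_genes, length(age_rank),
                   dimnames = list(programs$genes, NULL))
  for (a in seq_len(A)) {
    grade <- config$effect_size * pmax(0, 1 - abs(age_rank - a) / config$age_bandwidth)
    shifts[programs$age[[a]], ] <-
      matrix(grade, config$program_size, length(age_rank), byrow = TRUE)
  }
  shifts
}

#' Generate a synthetic age-labeled reference atlas
#'
#' Emits `n_cells_per_group` cells per age level; each cell carries a true
#' age label and cell type, expression follows the program model of
#' [simulation_config()].
#'
#' @param config a [simulation_config()].
#' @return a list with `matrix` (raw counts [expr_matrix]), `annotation`
#'   (tibble: cell_id, sample, cell_type, age_label) and `truth` (the
#'   [gene_programs()] layout).
#' @export
generate_reference_atlas <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  programs <- gene_programs(config)
  A <- length(config$age_levels)
  n_cells <- A * config$n_cells_per_group
  local_rng(config$seed, {
    age_rank <- rep(seq_len(A), each = config$n_cells_per_group)
    cell_type <- sample(config$cell_types, n_cells, replace = TRUE)
    shifts <- age_shift_matrix(config, programs, age_rank)
    for (ct in config$cell_types) {
      shifts[programs$type[[ct]], cell_type == ct] <-
        shifts[programs$type[[ct]], cell_type == ct] + config$effect_size
    }
    cell_ids <- sprintf("ref_%04d", seq_len(n_cells))
    mat <- simulate_counts(config, shifts, cell_ids)
    list(
      matrix = mat,
      annotation = tibble(
        cell_id = cell_ids,
        sample = "reference",
        cell_type = cell_type,
        age_label = config$age_levels[age_rank]
      ),
      truth = programs
    )
  })
}

#' Generate a synthetic tumor query atlas with hidden young/old truth
#'
#' Query cells mix a "young-like" population (ages sampled from the
#' GW7-GW14 programs) and an "old-like" population (GW16 onward); all tumor
#' cells activate the malignancy program and the anti-senescence program,
#' and young-like cells activate the anti-senescence program more strongly
#' (the planted signature recovered by the downstream derivation).
#'
#' @param config a [simulation_config()]; `young_fraction` sets the hidden
#'   bin mixture and `2 * n_cells_per_group` cells are emitted.
#' @param ref output of [generate_reference_atlas()] with a compatible gene
#'   universe.
#' @return a list with `matrix`, `annotation` (cell_id, sample, cell_type,
#'   true_bin, true_age) and `truth`.
#' @export
generate_query_atlas <- function(config, ref) {
  stopifnot(inherits(config, "simulation_config"))
  programs <- gene_programs(config)
  if (!identical(programs$genes, gene_ids(ref$matrix))) {
    abort("Query config gene universe does not match the reference atlas.")
  }
  A <- length(config$age_levels)
  young <- young_age_levels(config$age_levels)
  old <- setdiff(config$age_levels, young)
  n_cells <- 2L * config$n_cells_per_group
  local_rng(config$seed + 1L, {
    n_young <- rbinom(1, n_cells, config$young_fraction)
    true_bin <- sample(c(rep("young", n_young), rep("old", n_cells - n_young)))
    age_label <- ifelse(true_bin == "young",
                        sample(young, n_cells, replace = TRUE),
                        sample(old, n_cells, replace = TRUE))
    age_rank <- match(age_label, config$age_levels)
    shifts <- age_shift_matrix(config, programs, age_rank)
    lineage <- sample(config$cell_types[seq_len(min(2, length(config$cell_types)))],
                      n_cells, replace = TRUE)
    for (ct in unique(lineage)) {
      shifts[programs$type[[ct]], lineage == ct] <-
        shifts[programs$type[[ct]], lineage == ct] + config$effect_size
    }
    shifts[programs$malignancy, ] <- shifts[programs$malignancy, ] + config$effect_size
    shifts[programs$anti_senescence, ] <-
      shifts[programs$anti_senescence, ] + 0.75 * config$effect_size
    shifts[programs$anti_senescence, true_bin == "young"] <-
      shifts[programs$anti_senescence, true_bin == "young"] + 1.5 * config$effect_size
    cell_ids <- sprintf("tum_%04d", seq_len(n_cells))
    mat <- simulate_counts(config, shifts, cell_ids)
    list(
      matrix = mat,
      annotation = tibble(
        cell_id = cell_ids,
        sample = "tumor",
        cell_type = "malignant",
        true_bin = true_bin,
        true_age = age_label
      ),
      truth = programs
    )
  })
}

#' Generate a synthetic cross-species brain-aging atlas
#'
#' Emits young and old cells in the orthologous gene namespace defined by
#' `map`; the mapped orthologs of `young_up` (default: the config's planted
#' anti-senescence program) are upregulated in young cells by
#' `effect_size`.
#'
#' @param config a [simulation_config()].
#' @param map an [ortholog_map()] covering a subset of the human universe.
#' @param young_up human-namespace genes to plant as young-up (default the
#'   anti-senescence program).
#' @return a list with `matrix`, `annotation` (cell_id, sample, cell_type,
#'   age_label in \{young, old\}) and `truth$young_up_orthologs`.
#' @export
generate_aging_atlas <- function(config, map, young_up = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!nrow(map)) abort("Ortholog map is empty.")
  programs <- gene_programs(config)
  young_up <- young_up %||% programs$anti_senescence
  map <- map[map$human_symbol %in% programs$genes, , drop = FALSE]
  ortho_genes <- unique(map$ortholog_symbol)
  planted <- unique(map$ortholog_symbol[map$human_symbol %in% young_up])
  n_per <- config$n_cells_per_group
  local_rng(config$seed + 2L, {
    age_label <- rep(c("young", "old"), each = n_per)
    shifts <- matrix(0, length(ortho_genes), 2L * n_per,
                     dimnames = list(ortho_genes, NULL))
    shifts[planted, age_label == "young"] <- config$effect_size
    cfg <- config
    cfg$n_genes <- length(ortho_genes)
    cell_ids <- sprintf("age_%04d", seq_len(2L * n_per))
    baseline <- rnorm(cfg$n_genes, 0, 0.5)
    w <- exp(baseline + shifts)
    p <- sweep(w, 2, colSums(w), "/")
    lib <- rlnorm(2L * n_per, log(cfg$library_size_mean), cfg$library_size_sdlog)
    mu <- sweep(p, 2, lib, "*")
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 1 / cfg$dispersion),
                     nrow = cfg$n_genes, dimnames = list(ortho_genes, cell_ids))
    list(
      matrix = expr_matrix(counts, layer = "raw_counts"),
      annotation = tibble(cell_id = cell_ids, sample = "aging",
                          cell_type = "brain", age_label = age_label),
      truth = list(young_up_orthologs = planted, young_up_human = intersect(young_up, map$human_symbol))
    )
  })
}

#' Default synthetic ortholog map (casing convention)
#'
#' Maps each human-style upper-case symbol to a capitalized ortholog symbol
#' (`GENE0001` to `Gene0001`), the usual human/mouse casing convention.
#' A stand-in for a curated homology table; replace with any two-column map
#' for real data.
#'
#' @param genes human-namespace gene symbols.
#' @return an [ortholog_map()] tibble.
#' @export
casing_ortholog_map <- function(genes) {
  cap <- paste0(substr(genes, 1, 1), tolower(substring(genes, 2)))
  ortholog_map(genes, cap)
}

#' Survival-cohort simulation configuration
#'
#' @param n_samples number of patients.
#' @param n_genes number of genes in the expression table.
#' @param causal_genes gene labels carrying nonzero log-hazard
#'   coefficients; must lie in the gene universe `GENE0001...`.
#' @param betas per-causal-gene log-hazard coefficients (per expression
#'   unit).
#' @param baseline_scale scale of the exponential baseline hazard.
#' @param censor_rate target fraction of censored samples in \[0, 1).
#' @param seed integer RNG seed.
#' @return a `survival_sim_config` list.
#' @export
survival_sim_config <- function(n_samples = 300,
                                n_genes = 100,
                                causal_genes = character(),
                                betas = numeric(),
                                baseline_scale = 1,
                                censor_rate = 0.2,
                                seed = 1L) {
  if (length(causal_genes) != length(betas)) {
    abort("`causal_genes` and `betas` must have equal length.")
  }
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  if (!all(causal_genes %in% genes)) abort("`causal_genes` outside the gene universe.")
  if (censor_rate < 0 || censor_rate >= 1) abort("`censor_rate` must lie in [0, 1).")
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    causal_genes = as.character(causal_genes), betas = as.numeric(betas),
    baseline_scale = baseline_scale, censor_rate = censor_rate,
    seed = as.integer(seed)
  ), class = "survival_sim_config")
}

#' Generate a synthetic bulk survival cohort with planted hazards
#'
#' Event times follow a proportional-hazards model with exponential
#' baseline and linear predictor `sum(beta_g * expr_g)` over the causal
#' genes. Causal genes are emitted as on/off bimodal expression (Bernoulli
#' 0/1 plus small jitter), emulating expression-subtype markers, so the
#' planted per-unit hazard ratio `exp(beta)` is also the high-vs-low group
#' hazard ratio at a median split. Noise genes are standard normal.
#' Censoring is independent exponential, calibrated so the expected
#' censored fraction equals `censor_rate`.
#'
#' @param config a [survival_sim_config()].
#' @return a [cohort_data] with the planted truth in `$truth`.
#' @export
generate_survival_cohort <- function(config) {
  stopifnot(inherits(config, "survival_sim_config"))
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  local_rng(config$seed, {
    n <- config$n_samples
    expr <- matrix(rnorm(config$n_genes * n), nrow = config$n_genes,
                   dimnames = list(genes, sprintf("S%04d", seq_len(n))))
    for (g in config$causal_genes) {
      expr[g, ] <- rbinom(n, 1, 0.5) + rnorm(n, 0, 0.05)
    }
    lp <- if (length(config$causal_genes)) {
      as.vector(config$betas %*% expr[config$causal_genes, , drop = FALSE])
    } else rep(0, n)
    hazard <- exp(lp) / config$baseline_scale
    time_event <- rexp(n, rate = hazard)
    if (config$censor_rate > 0) {
      # P(C < T) with C ~ Exp(r), T_i ~ Exp(h_i) is mean(r / (r + h_i)).
      f <- function(r) mean(r / (r + hazard)) - config$censor_rate
      r <- stats::uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-10)$root
      cens <- rexp(n, rate = r)
      event <- as.integer(time_event <= cens)
      time <- pmin(time_event, cens)
    } else {
      event <- rep(1L, n)
      time <- time_event
    }
    cohort_data_from_parts(
      expression = expr, time = time, event = event,
      truth = list(causal_genes = config$causal_genes, betas = config$betas)
    )
  })
}

#' Generate a multi-sample atlas with planted expression programs
#'
#' Builds the fixture for meta-program discovery: `n_samples` pseudo-tumors
#' each containing cells assigned to one of `n_programs` shared programs;
#' a cell's program genes get a log-mean shift of `program_effect`.
#'
#' @param n_programs number of shared planted programs.
#' @param n_samples number of samples (pseudo-tumors).
#' @param cells_per_sample cells per sample.
#' @param n_genes gene universe size.
#' @param program_size genes per program.
#' @param program_effect log-mean shift of a cell's active program.
#' @param seed integer RNG seed.
#' @return list with `matrix` (raw counts), `annotation` (cell_id, sample,
#'   true_program) and `truth$programs` (named list of gene vectors).
#' @export
generate_program_atlas <- function(n_programs = 4, n_samples = 6,
                                   cells_per_sample = 120, n_genes = 500,
                                   program_size = 30, program_effect = 2,
                                   seed = 1L) {
  if (n_genes < n_programs * program_size) abort("Gene universe too small for programs.")
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  programs <- setNames(
    lapply(seq_len(n_programs), function(i) {
      genes[((i - 1) * program_size + 1):(i * program_size)]
    }),
    paste0("P", seq_len(n_programs))
  )
  local_rng(seed, {
    n_cells <- n_samples * cells_per_sample
    sample_id <- rep(sprintf("sample%d", seq_len(n_samples)), each = cells_per_sample)
    true_program <- sample(names(programs), n_cells, replace = TRUE)
    shifts <- matrix(0, n_genes, n_cells, dimnames = list(genes, NULL))
    for (p in names(programs)) {
      shifts[programs[[p]], true_program == p] <- program_effect
    }
    baseline <- rnorm(n_genes, 0, 0.5)
    w <- exp(baseline + shifts)
    p <- sweep(w, 2, colSums(w), "/")
    lib <- rlnorm(n_cells, log(5000), 0.25)
    mu <- sweep(p, 2, lib, "*")
    cell_ids <- sprintf("mp_%04d", seq_len(n_cells))
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 1 / 0.3),
                     nrow = n_genes, dimnames = list(genes, cell_ids))
    list(
      matrix = expr_matrix(counts, layer = "raw_counts"),
      annotation = tibble(cell_id = cell_ids, sample = sample_id,
                          true_program = true_program),
      truth = list(programs = programs)
    )
  })
}
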