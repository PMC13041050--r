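#' Bulk survival cohort container
#'
#' Binds a genes x samples expression table (log2(TPM+1) scale) to survival
#' time, event status and optional clinical covariates, with sample
#' alignment enforced.
#'
#' @param table a data frame with columns `sample_id`, `time`, `event`,
#'   optional covariate columns named in `covariates`, and one column per
#'   gene.
#' @param covariates names of the clinical covariate columns.
#' @return a `cohort_data` list: `expression` (genes x samples matrix),
#'   `time`, `event`, `covariates` (tibble), `sample_ids`.
#' @export
cohort_data <- function(table, covariates = character()) {
  table <- as_tibble(table)
  needed <- c("sample_id", "time", "event")
  if (!all(needed %in% names(table))) {
    abort("Cohort table needs `sample_id`, `time`, `event` columns.")
  }
  gene_cols <- setdiff(names(table), c(needed, covariates))
  expr <- t(as.matrix(table[gene_cols]))
  colnames(expr) <- table$sample_id
  cohort_data_from_parts(
    expression = expr, time = table$time, event = table$event,
    covariates = table[covariates]
  )
}

#' @rdname cohort_data
#' @param expression genes x samples numeric matrix with dimnames.
#' @param time,event survival columns (`time > 0`, `event` in \{0, 1\}).
#' @param truth optional list of planted ground truth (simulations).
#' @export
cohort_data_from_parts <- function(expression, time, event,
                                   covariates = NULL, truth = NULL) {
  stopifnot(is.matrix(expression), !is.null(rownames(expression)),
            !is.null(colnames(expression)))
  n <- ncol(expression)
  if (length(time) != n || length(event) != n) abort("Survival columns misaligned with samples.")
  if (any(time <= 0)) abort("`time` must be positive.")
  if (!all(event %in% c(0, 1))) abort("`event` must be 0/1.")
  covariates <- if (is.null(covariates)) tibble(.rows = n) else as_tibble(covariates)
  if (nrow(covariates) != n) abort("Covariates misaligned with samples.")
  structure(list(
    expression = expression, time = as.numeric(time), event = as.integer(event),
    covariates = covariates, sample_ids = colnames(expression), truth = truth
  ), class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data> %d genes x %d samples, %d events, %d covariates\n",
              nrow(x$expression), ncol(x$expression), sum(x$event),
              ncol(x$covariates)))
  invisible(x)
}

# Flat table form used by write_cohort().
as_cohort_table <- function(cohort) {
  bind_cols(
    tibble(sample_id = cohort$sample_ids, time = cohort$time, event = cohort$event),
    cohort$covariates,
    as_tibble(t(cohort$expression))
  )
}

#' Ensemble selection configuration
#'
#' @param n_lasso_runs number of repeated Lasso runs (penalty chosen by
#'   seeded cross-validation in each run).
#' @param lasso_min_count retention threshold: a gene is kept when selected
#'   in strictly more than this many runs.
#' @param univariate_p_max p-value cutoff of the univariate Cox prefilter.
#' @param nfolds cross-validation folds for penalized fits.
#' @param roster selector roster, see [selector_roster()].
#' @return a `selection_config` list.
#' @export
selection_config <- function(n_lasso_runs = 1000, lasso_min_count = 50,
                             univariate_p_max = 0.05, nfolds = 10,
                             roster = selector_roster()) {
  if (n_lasso_runs < 1) abort("`n_lasso_runs` must be >= 1.")
  if (lasso_min_count >= n_lasso_runs) abort("`lasso_min_count` must be below `n_lasso_runs`.")
  if (!nrow(roster)) abort("Roster must be nonempty.")
  structure(list(n_lasso_runs = as.integer(n_lasso_runs),
                 lasso_min_count = lasso_min_count,
                 univariate_p_max = univariate_p_max,
                 nfolds = as.integer(nfolds), roster = roster),
            class = "selection_config")
}

#' The 18-model selector roster
#'
#' Enumerates the ensemble: Lasso; elastic net at alpha 0.1-0.9 (nine
#' models); stepwise Cox in forward, backward and bidirectional flavors;
#' and Boruta, CoxBoost, random survival forest, Xgboost and SVM-RFE —
#' 1 + 9 + 3 + 5 = 18 model configurations. Lasso, the elastic nets, the
#' stepwise variants, the random survival forest (ranger) and Xgboost
#' (survival:cox) have built-in implementations; Boruta, CoxBoost and
#' SVM-RFE are roster entries behind the pluggable interface (supply an
#' implementation via the `impls` argument of [run_selector_roster()]).
#'
#' @return a tibble: `model_id`, `family`, `parameter`, `implemented`.
#' @export
selector_roster <- function() {
  bind_rows(
    tibble(model_id = "lasso", family = "penalized_cox", parameter = "alpha=1",
           implemented = TRUE),
    tibble(model_id = sprintf("enet_%.1f", seq(0.1, 0.9, by = 0.1)),
           family = "penalized_cox",
           parameter = sprintf("alpha=%.1f", seq(0.1, 0.9, by = 0.1)),
           implemented = TRUE),
    tibble(model_id = c("stepcox_forward", "stepcox_backward", "stepcox_both"),
           family = "stepwise_cox",
           parameter = c("direction=forward", "direction=backward", "direction=both"),
           implemented = TRUE),
    tibble(model_id = c("boruta", "coxboost", "rsf", "xgboost", "svm_rfe"),
           family = c("wrapper", "boosting", "forest", "boosting", "wrapper"),
           parameter = "",
           implemented = c(FALSE, FALSE, TRUE, TRUE, FALSE))
  )
}

#' Univariate Cox prefilter
#'
#' Fits one proportional-hazards model per gene and reports the Wald p
#' value; genes with `p_value < p_max` are flagged as retained. Constant
#' genes are skipped with a message.
#'
#' @param cohort a [cohort_data].
#' @param p_max retention cutoff.
#' @param genes genes to screen (default all).
#' @return tibble: `gene`, `coef`, `hr`, `p_value`, `retained`.
#' @export
univariate_cox_screen <- function(cohort, p_max = 0.05, genes = NULL) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (ncol(cohort$expression) < 20 || sum(cohort$event) < 5) {
    abort("Need at least 20 samples with at least 5 events.")
  }
  genes <- genes %||% rownames(cohort$expression)
  y <- survival::Surv(cohort$time, cohort$event)
  skipped <- character()
  rows <- map(genes, function(g) {
    x <- cohort$expression[g, ]
    if (var(x) == 0) {
      skipped <<- c(skipped, g)
      return(NULL)
    }
    fit <- survival::coxph(y ~ x)
    s <- summary(fit)
    tibble(gene = g, coef = unname(stats::coef(fit)),
           hr = unname(exp(stats::coef(fit))),
           p_value = s$coefficients[1, "Pr(>|z|)"])
  })
  if (length(skipped)) {
    inform(sprintf("Skipped %d constant gene(s): %s", length(skipped),
                   paste(head(skipped, 5), collapse = ", ")))
  }
  out <- list_rbind(rows)
  out$retained <- out$p_value < p_max
  out
}

# Penalized Cox selection for one run: nonzero coefficients at the
# cross-validated penalty, with seeded fold assignment. The parsimony rule
# (lambda.1se: largest penalty within one SE of the CV optimum) is used so
# a run selects a sparse, stable support rather than the noise-padded
# lambda.min support.
penalized_cox_once <- function(x, y, alpha, nfolds, seed) {
  local_rng(seed, {
    foldid <- sample(rep_len(seq_len(nfolds), nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, family = "cox", alpha = alpha, foldid = foldid)
    cf <- as.matrix(stats::coef(cv, s = "lambda.1se"))
    rownames(cf)[cf[, 1] != 0]
  })
}

#' Repeated Lasso stability selection
#'
#' Runs an L1-penalized proportional-hazards fit `n_runs` times; each run
#' reseeds the cross-validation fold assignment used to pick the penalty,
#' and a gene is counted when its coefficient is nonzero at the selected
#' penalty. Genes selected in strictly more than `min_count` runs are
#' retained. A run whose fit fails is recorded as selecting nothing.
#'
#' @param cohort a [cohort_data].
#' @param genes candidate genes (e.g. the univariate survivors).
#' @param n_runs,min_count run count and retention threshold.
#' @param nfolds cross-validation folds.
#' @param seed base seed; run r uses `seed + r`.
#' @return list: `counts` (tibble `gene`, `count`), `retained` (character),
#'   `n_failed`.
#' @export
repeated_lasso_select <- function(cohort, genes, n_runs = 1000, min_count = 50,
                                  nfolds = 10, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (!length(genes)) abort("`genes` must be nonempty.")
  x <- t(cohort$expression[genes, , drop = FALSE])
  y <- survival::Surv(cohort$time, cohort$event)
  counts <- setNames(integer(length(genes)), genes)
  n_failed <- 0L
  for (r in seq_len(n_runs)) {
    sel <- tryCatch(
      penalized_cox_once(x, y, alpha = 1, nfolds = nfolds, seed = seed + r),
      error = function(e) {
        n_failed <<- n_failed + 1L
        character()
      }
    )
    counts[sel] <- counts[sel] + 1L
  }
  if (n_failed) inform(sprintf("%d of %d Lasso runs failed and selected nothing.", n_failed, n_runs))
  list(counts = tibble(gene = genes, count = unname(counts)),
       retained = genes[counts > min_count],
       n_failed = n_failed)
}

# Stepwise Cox selection via AIC.
stepcox_select <- function(cohort, genes, direction) {
  df <- as.data.frame(t(cohort$expression[genes, , drop = FALSE]))
  df$.time <- cohort$time
  df$.event <- cohort$event
  full_formula <- stats::as.formula(
    paste("survival::Surv(.time, .event) ~", paste(genes, collapse = " + ")))
  null_formula <- survival::Surv(.time, .event) ~ 1
  start <- if (direction == "forward") {
    survival::coxph(null_formula, data = df)
  } else {
    survival::coxph(full_formula, data = df)
  }
  fit <- suppressWarnings(stats::step(
    start, scope = list(lower = null_formula, upper = full_formula),
    direction = if (direction == "both") "both" else direction,
    trace = 0
  ))
  intersect(genes, attr(stats::terms(fit), "term.labels"))
}

rsf_select <- function(cohort, genes, seed) {
  if (!requireNamespace("ranger", quietly = TRUE)) {
    abort("The rsf selector needs the `ranger` package.")
  }
  df <- as.data.frame(t(cohort$expression[genes, , drop = FALSE]))
  df$.time <- cohort$time
  df$.event <- cohort$event
  fit <- ranger::ranger(
    survival::Surv(.time, .event) ~ ., data = df,
    importance = "permutation", num.trees = 300, seed = seed
  )
  names(fit$variable.importance)[fit$variable.importance > 0]
}

xgboost_select <- function(cohort, genes, seed) {
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    abort("The xgboost selector needs the `xgboost` package.")
  }
  x <- t(cohort$expression[genes, , drop = FALSE])
  label <- ifelse(cohort$event == 1, cohort$time, -cohort$time)
  local_rng(seed, {
    dtrain <- xgboost::xgb.DMatrix(x, label = label, nthread = 1)
    fit <- xgboost::xgb.train(
      params = list(objective = "survival:cox", max_depth = 2, eta = 0.3,
                    nthread = 1),
      data = dtrain, nrounds = 50, verbose = 0
    )
    imp <- xgboost::xgb.importance(model = fit)
    intersect(genes, imp$Feature[imp$Gain > 0])
  })
}

#' Run the selector roster over one or more cohorts
#'
#' Applies every implemented roster model to every cohort and records the
#' selection indicators. The Lasso entry is the repeated stability
#' selection of [repeated_lasso_select()]; elastic nets are single seeded
#' cross-validated fits; stepwise Cox uses AIC; the random survival forest
#' keeps positive-permutation-importance genes; Xgboost keeps
#' positive-gain genes. Unimplemented roster entries (Boruta, CoxBoost,
#' SVM-RFE) are skipped unless an implementation is supplied in `impls`.
#'
#' @param cohorts named list of [cohort_data] objects.
#' @param genes candidate genes.
#' @param config a [selection_config()].
#' @param seed base seed.
#' @param impls named list of custom selector functions
#'   `function(cohort, genes, seed) -> character` keyed by `model_id`,
#'   overriding or completing the roster.
#' @return long indicator tibble: `gene`, `model_id`, `cohort`, `selected`.
#' @export
run_selector_roster <- function(cohorts, genes, config = selection_config(),
                                seed = 1L, impls = list()) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1, !is.null(names(cohorts)))
  roster <- config$roster
  rows <- list()
  for (cn in names(cohorts)) {
    cohort <- cohorts[[cn]]
    for (i in seq_len(nrow(roster))) {
      mid <- roster$model_id[i]
      sel <- if (!is.null(impls[[mid]])) {
        impls[[mid]](cohort, genes, seed)
      } else if (grepl("^(lasso|enet)", mid)) {
        if (mid == "lasso") {
          repeated_lasso_select(cohort, genes, n_runs = config$n_lasso_runs,
                                min_count = config$lasso_min_count,
                                nfolds = config$nfolds, seed = seed)$retained
        } else {
          alpha <- as.numeric(sub("enet_", "", mid))
          x <- t(cohort$expression[genes, , drop = FALSE])
          y <- survival::Surv(cohort$time, cohort$event)
          tryCatch(penalized_cox_once(x, y, alpha, config$nfolds, seed),
                   error = function(e) character())
        }
      } else if (grepl("^stepcox", mid)) {
        stepcox_select(cohort, genes, sub("stepcox_", "", mid))
      } else if (mid == "rsf") {
        rsf_select(cohort, genes, seed)
      } else if (mid == "xgboost") {
        xgboost_select(cohort, genes, seed)
      } else {
        NULL  # unimplemented, no custom impl: skipped
      }
      if (is.null(sel)) next
      rows[[length(rows) + 1L]] <- tibble(
        gene = genes, model_id = mid, cohort = cn,
        selected = as.integer(genes %in% sel)
      )
    }
  }
  list_rbind(rows)
}

#' Aggregate selection indicators into a frequency table
#'
#' Per gene and cohort, the frequency is the number of models selecting
#' the gene; the average frequency is the mean across cohorts (the sum is
#' available via `summary = "sum"`). Genes are ranked by decreasing
#' aggregate, ties broken lexicographically (flagged in `rank_tie`).
#'
#' @param indicators long tibble from [run_selector_roster()] (`gene`,
#'   `model_id`, `cohort`, `selected`).
#' @param summary `"mean"` (average frequency) or `"sum"`.
#' @return a `frequency_table` tibble: `gene`, one `freq_<cohort>` column
#'   per cohort, `average_frequency`, `rank`, `rank_tie`.
#' @export
aggregate_frequency <- function(indicators, summary = c("mean", "sum")) {
  summary <- match.arg(summary)
  stopifnot(all(c("gene", "model_id", "cohort", "selected") %in% names(indicators)))
  per_cohort <- indicators |>
    group_by(.data$gene, .data$cohort) |>
    summarise(frequency = sum(.data$selected), .groups = "drop")
  wide <- tidyr::pivot_wider(per_cohort, names_from = "cohort",
                             values_from = "frequency", names_prefix = "freq_")
  agg <- per_cohort |>
    group_by(.data$gene) |>
    summarise(average_frequency = if (summary == "mean") mean(.data$frequency)
              else sum(.data$frequency), .groups = "drop")
  out <- left_join(wide, agg, by = "gene") |>
    arrange(desc(.data$average_frequency), .data$gene)
  out$rank <- seq_len(nrow(out))
  out$rank_tie <- duplicated(out$average_frequency) |
    duplicated(out$average_frequency, fromLast = TRUE)
  structure(out, class = c("frequency_table", class(tibble())))
}

#' Median-split survival analysis for one gene
#'
#' Dichotomizes samples at the gene's median expression (values equal to
#' the median go to the low stratum, so odd cohorts put `ceiling(n/2)`
#' samples in the low group), then reports the high-vs-low Cox hazard
#' ratio with 95% CI and the log-rank p value.
#'
#' @param cohort a [cohort_data].
#' @param gene gene label.
#' @return a `medsplit_result` one-row tibble: `gene`, `hr`, `ci_lower`,
#'   `ci_upper`, `logrank_p`, `n_low`, `n_high`.
#' @export
median_split_logrank <- function(cohort, gene) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (!gene %in% rownames(cohort$expression)) abort(paste0("Gene not in cohort: ", gene))
  x <- cohort$expression[gene, ]
  if (var(x) == 0) abort(paste0("Zero-variance gene: ", gene))
  high <- x > median(x)
  if (!any(high) || all(high)) abort("Median split produced an empty stratum.")
  y <- survival::Surv(cohort$time, cohort$event)
  fit <- survival::coxph(y ~ high)
  s <- summary(fit)
  lr <- survival::survdiff(y ~ high)
  structure(tibble(
    gene = gene,
    hr = unname(s$conf.int[1, "exp(coef)"]),
    ci_lower = unname(s$conf.int[1, "lower .95"]),
    ci_upper = unname(s$conf.int[1, "upper .95"]),
    logrank_p = stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE),
    n_low = sum(!high), n_high = sum(high)
  ), class = c("medsplit_result", class(tibble())))
}

#' Multivariate Cox model for a gene adjusted for covariates
#'
#' Proportional-hazards fit of survival on the gene plus clinical
#' covariates (complete cases). Near-collinear predictor pairs
#' (|r| > 0.999) are an error naming the pair.
#'
#' @param cohort a [cohort_data].
#' @param gene gene label.
#' @param covariates data frame of covariates (default the cohort's own).
#' @return a `multicox_result` tibble with one row per term: `term`,
#'   `coef`, `hr`, `ci_lower`, `ci_upper`, `p_value`.
#' @export
multivariate_cox <- function(cohort, gene, covariates = NULL) {
  stopifnot(inherits(cohort, "cohort_data"))
  covariates <- as_tibble(covariates %||% cohort$covariates)
  if (!ncol(covariates)) abort("No covariates supplied.")
  df <- bind_cols(tibble(!!gene := cohort$expression[gene, ]), covariates)
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  num <- df[vapply(df, is.numeric, logical(1))]
  if (ncol(num) >= 2) {
    cm <- suppressWarnings(cor(num))
    cm[!upper.tri(cm)] <- 0
    bad <- which(abs(cm) > 0.999, arr.ind = TRUE)
    if (nrow(bad)) {
      abort(sprintf("Collinear predictors: %s and %s.",
                    colnames(num)[bad[1, 2]], rownames(num)[bad[1, 1]]))
    }
  }
  y <- survival::Surv(cohort$time[keep], cohort$event[keep])
  fit <- survival::coxph(y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    abort(paste0("Aliased term(s) in the Cox fit: ",
                 paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", ")))
  }
  s <- summary(fit)
  structure(tibble(
    term = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hr = s$conf.int[, "exp(coef)"],
    ci_lower = s$conf.int[, "lower .95"],
    ci_upper = s$conf.int[, "upper .95"],
    p_value = s$coefficients[, "Pr(>|z|)"]
  ), class = c("multicox_result", class(tibble())))
}
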