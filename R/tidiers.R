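#' Broom-style tidiers for pipeline results
#'
#' `tidy()` returns the per-unit table of a result; `glance()` returns a
#' one-row summary.
#'
#' @param x a result object.
#' @param ... unused.
#' @return a tibble.
#' @name projage-tidiers
NULL

#' @rdname projage-tidiers
#' @export
tidy.deg_table <- function(x, ...) as_tibble(x)

#' @rdname projage-tidiers
#' @export
glance.deg_table <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_significant = sum(x$p_adj < 0.05),
    adjust_method = x$adjust_method[1]
  )
}

#' @rdname projage-tidiers
#' @export
tidy.projection_result <- function(x, ...) as_tibble(x)

#' @rdname projage-tidiers
#' @export
glance.projection_result <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    n_unassigned = sum(x$projected_age == "unassigned"),
    mean_transfer_score = mean(x$transfer_score),
    frac_young = if ("age_bin" %in% names(x)) mean(x$age_bin == "young", na.rm = TRUE) else NA_real_
  )
}

#' @rdname projage-tidiers
#' @export
tidy.frequency_table <- function(x, ...) as_tibble(x)

#' @rdname projage-tidiers
#' @export
glance.frequency_table <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_cohorts = sum(startsWith(names(x), "freq_")),
    top_gene = x$gene[x$rank == 1][1],
    top_frequency = max(x$average_frequency)
  )
}

#' @rdname projage-tidiers
#' @export
tidy.medsplit_result <- function(x, ...) {
  tibble(term = paste0(x$gene, "_high"), estimate = log(x$hr), hr = x$hr,
         conf.low = x$ci_lower, conf.high = x$ci_upper, p.value = x$logrank_p)
}

#' @rdname projage-tidiers
#' @export
glance.medsplit_result <- function(x, ...) {
  tibble(n = x$n_low + x$n_high, n_low = x$n_low, n_high = x$n_high,
         logrank_p = x$logrank_p)
}

#' @rdname projage-tidiers
#' @export
tidy.multicox_result <- function(x, ...) {
  tibble(term = x$term, estimate = x$coef, hr = x$hr,
         conf.low = x$ci_lower, conf.high = x$ci_upper, p.value = x$p_value)
}

#' @rdname projage-tidiers
#' @export
tidy.meta_programs <- function(x, ...) {
  list_rbind(map(x, function(mp) {
    mutate(mp$gene_stats, mp_id = mp$mp_id,
           in_consensus = .data$gene %in% mp$consensus_genes)
  }))
}

#' @rdname projage-tidiers
#' @export
glance.meta_programs <- function(x, ...) {
  tibble(
    n_metaprograms = length(x),
    n_consensus_genes = sum(map_int(x, function(mp) length(mp$consensus_genes)))
  )
}
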