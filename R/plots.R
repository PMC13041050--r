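#' Volcano plot of a marker table
#'
#' @param object a `deg_table` from [rank_markers()].
#' @param spec optional [threshold_spec()] drawn as cutoff lines.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.deg_table <- function(object, spec = NULL, ...) {
  df <- mutate(as_tibble(object), neglog_p = -log10(pmax(.data$p_adj, 1e-300)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc, y = .data$neglog_p)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p")
  if (!is.null(spec)) {
    p <- p +
      ggplot2::geom_vline(xintercept = spec$log2fc_min, linetype = "dashed") +
      ggplot2::geom_hline(yintercept = -log10(spec$padj_max), linetype = "dashed")
  }
  p
}

#' Lollipop plot of selection frequencies
#'
#' @param object a `frequency_table` from [aggregate_frequency()].
#' @param top_n genes shown (by rank).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.frequency_table <- function(object, top_n = 15, ...) {
  df <- filter(as_tibble(object), .data$rank <= top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$average_frequency,
                                   y = stats::reorder(.data$gene, .data$average_frequency))) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = stats::reorder(.data$gene, .data$average_frequency))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "average selection frequency", y = NULL)
}

#' Projected-age composition plot
#'
#' Bar chart of projected gestational-week labels, filled by age bin when
#' present.
#'
#' @param object a `projection_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.projection_result <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$projected_age))
  if ("age_bin" %in% names(df)) {
    p <- p + ggplot2::geom_bar(ggplot2::aes(fill = .data$age_bin))
  } else {
    p <- p + ggplot2::geom_bar()
  }
  p + ggplot2::labs(x = "projected age", y = "cells")
}

#' Kaplan-Meier plot for a median-split gene
#'
#' @param cohort a [cohort_data].
#' @param gene gene label to dichotomize at its median.
#' @return a ggplot of the two survival curves.
#' @export
plot_median_split <- function(cohort, gene) {
  x <- cohort$expression[gene, ]
  stratum <- ifelse(x > median(x), "high", "low")
  fit <- survival::survfit(survival::Surv(cohort$time, cohort$event) ~ stratum)
  df <- tibble(
    time = fit$time,
    surv = fit$surv,
    stratum = rep(sub("stratum=", "", names(fit$strata)), fit$strata)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   color = .data$stratum)) +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time", y = "survival fraction", color = gene)
}
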