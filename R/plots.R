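# ggplot2 visualisations for the main result types

#' Plot a threshold scan
#'
#' Incremental R-squared across the p-value threshold grid, with the best
#' threshold marked.
#'
#' @param object A `pgs_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pgs_scan <- function(object, ...) {
  g <- object$grid
  ggplot2::ggplot(g, ggplot2::aes(x = .data$threshold, y = .data$r2_obs)) +
    ggplot2::geom_step(color = "grey30") +
    ggplot2::geom_vline(xintercept = object$best_threshold,
                        linetype = "dashed", color = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "p-value threshold (log scale)",
      y = expression(paste("incremental ", R^2)),
      title = sprintf("%s: best threshold %g (%d SNPs)", object$outcome,
                      object$best_threshold, object$best_n_snps)
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of association results
#'
#' Point estimates and 95% CIs per outcome; odds ratios are drawn on a log
#' scale with a reference line at 1, betas on a linear scale with a line
#' at 0.
#'
#' @param results Stacked `assoc_result` rows (one family at a time).
#' @return A ggplot.
#' @export
plot_association_forest <- function(results) {
  stopifnot(length(unique(results$family)) == 1)
  is_or <- results$family[1] == "binomial"
  ref <- if (is_or) 1 else 0
  p <- ggplot2::ggplot(results, ggplot2::aes(
    x = .data$estimate, y = stats::reorder(.data$outcome, .data$estimate)
  )) +
    ggplot2::geom_vline(xintercept = ref, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(
      x = if (is_or) "odds ratio per 1 SD of score" else "beta per 1 SD of score",
      y = NULL
    ) +
    ggplot2::theme_minimal()
  if (is_or) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a mediation decomposition
#'
#' Total effect, average direct effect and average causal mediation effect
#' with their resampling CIs.
#'
#' @param object A `mediation_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mediation_fit <- function(object, ...) {
  e <- object$estimates
  e$term <- factor(e$term, levels = c("acme", "ade", "total"),
                   labels = c("ACME", "ADE", "Total"))
  ggplot2::ggplot(e, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(
      x = if (object$family == "binomial") "risk difference per 1 SD" else "mean difference per 1 SD",
      y = NULL,
      title = sprintf("%s through %s", object$outcome, object$mediator)
    ) +
    ggplot2::theme_minimal()
}
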