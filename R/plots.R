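#' QQ plot of association p-values
#'
#' Observed versus expected -log10 p with the order-statistic confidence
#' band from [qq_table()].
#'
#' @param p_values Vector of p-values (or a `gwas_scan`, whose `p` column is
#'   used).
#' @param ci Band coverage (default 0.95).
#' @return A ggplot object.
#' @export
plot_qq <- function(p_values, ci = 0.95) {
  if (inherits(p_values, "gwas_scan")) p_values <- p_values$p
  qt <- qq_table(p_values, ci)
  ggplot2::ggplot(qt, ggplot2::aes(x = .data$expected)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey85") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_qq
#' @param object A `gwas_scan`.
#' @param ... Ignored.
#' @export
autoplot.gwas_scan <- function(object, ...) {
  plot_qq(object$p) +
    ggplot2::ggtitle(sprintf("%s (lambda GC = %.3f)",
                             attr(object, "phenotype"),
                             attr(object, "lambda_gc")))
}

#' Histogram of a CFSE well with the fitted dilution mixture
#'
#' @param object A `cfse_fit`.
#' @param intensities The fitted well's log10 intensities.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.cfse_fit <- function(object, intensities, ...) {
  grid <- seq(min(intensities), max(intensities), length.out = 400)
  dens <- rowSums(vapply(0:5, function(k) {
    object$w[k + 1] * dnorm(grid, object$mu0 - k * object$d, object$sigma)
  }, numeric(length(grid))))
  df <- tibble(x = intensities)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 80, fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = tibble(x = grid, y = dens),
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "red") +
    ggplot2::labs(x = "log10 CFSE intensity", y = "density") +
    ggplot2::theme_minimal()
}

#' Two-channel view of a gated flow sample
#'
#' @param object A `population_fit`.
#' @param sample The `flow_sample` that was fitted.
#' @param channels Two channel names to plot (default CD45RO vs CD62L).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.population_fit <- function(object, sample,
                                    channels = c("CD45RO", "CD62L"), ...) {
  df <- as_tibble(sample$events[, channels])
  df$population <- object$assignments
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[channels[1]]],
                                   y = .data[[channels[2]]],
                                   colour = .data$population)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::theme_minimal()
}

#' Per-gene correlations with proliferation, ordered bar chart
#'
#' @param corr Tibble from [correlate_genes()].
#' @param threshold Highlight genes below this permutation p (default 0.01).
#' @return A ggplot object.
#' @export
plot_signature_correlations <- function(corr, threshold = 0.01) {
  df <- dplyr::arrange(corr, .data$r)
  df$gene_id <- factor(df$gene_id, levels = df$gene_id)
  df$selected <- df$permutation_p < threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = .data$r,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "Pearson r with proliferation index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
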