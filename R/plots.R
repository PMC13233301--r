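#' QQ plot of per-probe p-values
#'
#' Observed versus expected \eqn{-\log_{10}} p quantiles with the identity
#' line and the genomic inflation factor in the subtitle.
#'
#' @param pvals P-value vector.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_qq <- function(pvals, title = "QQ plot") {
  dat <- qq_data(pvals)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(
      title = title,
      subtitle = sprintf("lambda = %.2f", genomic_inflation(pvals)),
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `ewas_result` and `meta_result` objects draw a QQ plot;
#' `concordance_summary` tibbles draw the concordant fraction per source
#' with the chance line at 1/2.
#'
#' @param object Result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ewas_result
#' @export
autoplot.ewas_result <- function(object, ...) {
  plot_qq(object$p.value, title = attr(object, "model") %||% "EWAS")
}

#' @rdname autoplot.ewas_result
#' @method autoplot meta_result
#' @export
autoplot.meta_result <- function(object, ...) {
  plot_qq(object$p.value, title = "blast meta-analysis")
}

#' @rdname autoplot.ewas_result
#' @method autoplot concordance_summary
#' @export
autoplot.concordance_summary <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), .data$n > 0)
  dat$frac <- dat$k / dat$n
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$source, y = .data$frac,
                                    fill = .data$bias)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::facet_wrap(~subgroup) +
    ggplot2::labs(x = NULL, y = "concordant fraction of overlaps") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Volcano plot of an EWAS result
#'
#' @param res An `ewas_result`.
#' @param alpha Family-wise level for the Bonferroni reference line.
#' @return A ggplot object.
#' @export
plot_volcano <- function(res, alpha = 0.05) {
  thr <- alpha / nrow(res)
  dat <- tibble::as_tibble(res)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate,
                                    y = -log10(.data$p.value))) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "coefficient (M-value units)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
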