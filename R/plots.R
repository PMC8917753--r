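#' Plot per-replicate cross-validation abilities
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$abilities,
                  ggplot2::aes(x = object$layer, y = .data$ability)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "prediction ability",
                  subtitle = sprintf("median of replicate medians = %.3f",
                                     object$median_of_medians)) +
    ggplot2::theme_minimal()
}

#' Plot grid-search abilities along each kernel weight
#' @param object A `grid_search_result`.
#' @param ... Unused.
#' @return A ggplot: ability against weight, one facet per kernel.
#' @export
autoplot.grid_search_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$grid,
                              cols = dplyr::all_of(object$kernel_names),
                              names_to = "kernel", values_to = "weight")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$weight, y = .data$ability)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~kernel) +
    ggplot2::labs(x = "kernel weight", y = "median prediction ability") +
    ggplot2::theme_minimal()
}

#' Plot a PCoA embedding
#' @param object A `pcoa_result`.
#' @param axes Which two axes to show (default 1:2).
#' @param ... Unused.
#' @return A ggplot of labelled items.
#' @export
autoplot.pcoa_result <- function(object, axes = 1:2, ...) {
  d <- tidy.pcoa_result(object)
  ax <- colnames(object$coordinates)[axes]
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                  label = .data$item)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", ax[1], object$percent_var[axes[1]]),
      y = sprintf("%s (%.1f%%)", ax[2], object$percent_var[axes[2]])
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of trait/metabolite correlations with significance stars
#' @param object An `omic_correlation`.
#' @param ... Unused.
#' @return A ggplot tile map; stars mark P < 0.05 / 0.01 / 0.001.
#' @export
autoplot.omic_correlation <- function(object, ...) {
  d <- expand.grid(var1 = rownames(object$r), var2 = colnames(object$r),
                   stringsAsFactors = FALSE)
  d$r <- as.vector(object$r)
  d$stars <- as.vector(object$stars)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$var1, y = .data$var2,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 2.5) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot 3'end prediction ability against window length
#' @param object A `three_prime_result`.
#' @param ... Unused.
#' @return A ggplot: ability vs N per layer, dashed full-length baseline.
#' @export
autoplot.three_prime_result <- function(object, ...) {
  tab <- object$table
  finite <- tab[is.finite(tab$N), ]
  base <- tab[!is.finite(tab$N), ]
  ggplot2::ggplot(finite, ggplot2::aes(x = .data$N, y = .data$median_ability,
                                       colour = .data$layer)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = base,
                        ggplot2::aes(yintercept = .data$median_ability,
                                     colour = .data$layer),
                        linetype = "dashed") +
    ggplot2::labs(x = "3'end window (bp)", y = "median prediction ability") +
    ggplot2::theme_minimal()
}
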