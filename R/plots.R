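#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar plot of mean variance fractions per effect
#'
#' @param object A \code{scpool_varpart} result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scpool_varpart <- function(object, ...) {
  s <- object$summary
  s$effect <- factor(s$effect, levels = vp_effects())
  ggplot2::ggplot(
    s, ggplot2::aes(x = .data$effect, y = .data$mean_fraction)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "mean fraction of variance",
      title = sprintf(
        "%s (k = %s, iteration %s)", object$cell_type,
        paste(object$pool_size, collapse = ","),
        paste(object$iteration, collapse = ",")
      )
    ) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Violin plot of per-gene variance fractions
#'
#' @param vp A \code{scpool_varpart} result.
#' @param effects Effects to show (default all but Residual).
#' @return A ggplot object.
#' @export
plot_variance_fractions <- function(vp, effects = setdiff(vp_effects(),
                                                          "Residual")) {
  res <- vp$results[vp$results$effect %in% effects, ]
  res$effect <- factor(res$effect, levels = vp_effects())
  ggplot2::ggplot(
    res, ggplot2::aes(x = .data$effect, y = .data$fraction)
  ) +
    ggplot2::geom_violin(fill = "grey85", scale = "width") +
    ggplot2::geom_boxplot(width = 0.1, outlier.size = 0.3) +
    ggplot2::labs(x = NULL, y = "fraction of variance per gene") +
    ggplot2::theme_bw()
}
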