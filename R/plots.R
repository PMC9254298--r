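#' @method autoplot srna_roc
#' @export
autoplot.srna_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (1 - specificity)",
                  y = "True positive rate (sensitivity)") +
    ggplot2::theme_minimal()
}

#' @method autoplot srna_cv
#' @export
autoplot.srna_cv <- function(object, ...) {
  roc <- roc_curve(object$scores$score, object$scores$label)
  autoplot(roc) +
    ggplot2::labs(
      title = object$settings$comparison,
      subtitle = sprintf("LOOCV AUC %.2f (95%% CI %.2f-%.2f), p = %.2g",
                         object$auc, object$ci[1], object$ci[2],
                         object$p_value)
    )
}

#' @method autoplot srna_voom
#' @export
autoplot.srna_voom <- function(object, ...) {
  amean <- rowMeans(object$E)
  sx <- amean + mean(log2(object$lib_size + 1)) - log2(1e6)
  pts <- tibble::tibble(x = sx, y = sqrt(apply(object$E, 1, sd)))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = object$trend,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "red", linewidth = 0.9) +
    ggplot2::labs(x = "Average log2 count", y = "sqrt(residual sd)",
                  title = "Mean-variance trend of log2-cpm") +
    ggplot2::theme_minimal()
}

#' Group-mean expression heatmap of the top features
#'
#' cpm-log2 transform, row z-scoring, group averaging, drawn as a tile map —
#' the group-level summary view of a DE result.
#'
#' @param ds An [srna_dataset()].
#' @param de An `srna_de` result; the `n_top` features with smallest q are
#'   shown.
#' @param factors Normalization factors or `NULL`.
#' @param n_top Number of features to display.
#' @return A ggplot object.
#' @export
plot_group_heatmap <- function(ds, de, factors = NULL, n_top = 25) {
  top <- dplyr::slice_min(tibble::as_tibble(de), .data$q_value, n = n_top,
                          with_ties = FALSE)
  x <- cpm_matrix(ds, factors, log = TRUE)
  z <- zscore_rows(x[top$feature_id, , drop = FALSE])
  gm <- group_means(z, ds$samples)
  long <- tibble::as_tibble(gm, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "group",
                        values_to = "mean_z")
  long$feature_id <- factor(long$feature_id, levels = rev(top$feature_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$feature_id,
                                     fill = .data$mean_z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean z") +
    ggplot2::theme_minimal()
}

#' @method autoplot srna_power
#' @export
autoplot.srna_power <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n_per_group, y = .data$power,
                               colour = factor(round(.data$logfc, 3)))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$power - 2 * .data$mc_se),
      ymax = pmin(1, .data$power + 2 * .data$mc_se))) +
    ggplot2::labs(x = "Samples per group", y = "Power at q < 0.05",
                  colour = "log2 FC") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
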