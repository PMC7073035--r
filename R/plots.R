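#' Plot a binned trajectory curve
#'
#' Mean pathway score per pseudotime bin with its 95% CI ribbon, optionally
#' overlaid with the polynomial fit.
#'
#' @param curve A `trajectory_curve` from [bin_curve()].
#' @param fit Optional `trajectory_fit` from [polyfit_curve()].
#' @return A ggplot object.
#' @export
plot_trajectory_curve <- function(curve, fit = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$midpoint, y = .data$mean,
                                           colour = .data$set_name,
                                           fill = .data$set_name)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "diffusion pseudotime", y = "mean pathway score",
                  colour = "gene set", fill = "gene set") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    at <- seq(min(curve$midpoint), max(curve$midpoint), length.out = 100)
    pred <- predict_curve(fit, at)
    p <- p + ggplot2::geom_line(
      data = pred,
      ggplot2::aes(x = .data$pseudotime, y = .data$fitted,
                   colour = .data$set_name),
      linetype = "dashed", inherit.aes = FALSE)
  }
  p
}

#' @export
autoplot.trajectory_curve <- function(object, ...) plot_trajectory_curve(object, ...)

#' Violin plot of pathway expression distributions
#'
#' One violin per species and pathway over the long pathway table (pooling
#' genes x replicates).
#'
#' @param p A `pathway_long` tibble.
#' @return A ggplot object.
#' @export
plot_pathway_violin <- function(p) {
  ggplot2::ggplot(p, ggplot2::aes(x = .data$pathway, y = .data$expr,
                                  fill = .data$pathway)) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = NULL, y = "log2(expression + 1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Heatmap of the sample-sample Spearman matrix
#'
#' @param x A `dsb_pca_spearman` object.
#' @return A ggplot object.
#' @export
plot_spearman_heatmap <- function(x) {
  rho <- x$spearman
  d <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(sample1 = rownames(rho)),
                     as_tibble(rho, .name_repair = "minimal")),
    -"sample1", names_to = "sample2", values_to = "rho")
  d$sample1 <- factor(d$sample1, levels = rownames(rho))
  d$sample2 <- factor(d$sample2, levels = colnames(rho))
  ggplot2::ggplot(d, ggplot2::aes(.data$sample1, .data$sample2, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(d$rho), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
autoplot.dsb_pca_spearman <- function(object, ...) {
  ggplot2::ggplot(object$coords,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$condition %||% .data$species)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$var_explained[2]),
      colour = NULL) +
    ggplot2::theme_minimal()
}
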