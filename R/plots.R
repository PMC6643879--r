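#' Plot predictive ability against training-set size
#'
#' Mean replicate `r_MP` (± one SD ribbon) per training size, colored by
#' trait and faceted by scheme/marker set where several are present.
#'
#' @param object A `gs_cv` tibble (or several row-bound together).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gs_cv <- function(object, ...) {
  s <- cv_summary(object)
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$n_train, y = .data$mean_r,
                                       colour = .data$trait)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_r - .data$sd_r,
                   ymax = .data$mean_r + .data$sd_r, fill = .data$trait),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training-set size", y = "predictive ability (r)") +
    ggplot2::theme_minimal()
  if (length(unique(s$scheme)) > 1 || length(unique(s$marker_set)) > 1) {
    p <- p + ggplot2::facet_grid(marker_set ~ scheme)
  }
  p
}

#' Plot the first two principal components of a genotype PCA
#'
#' @param object A `gs_pca` from [genotype_pca()].
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2, colored by population, with variance
#'   shares in the axis labels.
#' @export
autoplot.gs_pca <- function(object, ...) {
  ve <- object$var_explained$pct
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                  y = sprintf("PC2 (%.1f%%)", ve[2])) +
    ggplot2::theme_minimal()
}

#' Plot the structure-inflation decomposition
#'
#' Per-line mean predicted GEBVs against observed BLUPs, colored by
#' population, with the overall and within-population correlations in the
#' subtitle — between-population mean separation shows up as clusters
#' strung along the diagonal.
#'
#' @param object An `inflation_report` from [inflation_decomposition()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.inflation_report <- function(object, ...) {
  d <- attr(object, "data")
  overall <- object$r[object$population == "overall"]
  within <- object$r[object$population != "overall"]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$blup, y = .data$mean_gebv,
                                  colour = .data$population)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(
      x = "observed BLUP", y = "mean predicted GEBV",
      subtitle = sprintf("overall r = %.2f; within-population r = %s",
                         overall,
                         paste(sprintf("%.2f", within), collapse = ", "))
    ) +
    ggplot2::theme_minimal()
}
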