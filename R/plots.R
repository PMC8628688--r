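#' Plot the fusion-weight scan
#'
#' Cross-validated AUC against the spatial weight, with the selected weight
#' marked.
#'
#' @param object A [scan_weights()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fusion_result <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$w, y = .data$cv_auc)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_vline(xintercept = object$w_star, linetype = "dashed") +
    ggplot2::annotate("text", x = object$w_star, y = min(object$grid$cv_auc),
                      label = sprintf("w* = %.2f", object$w_star),
                      hjust = -0.1, vjust = 0) +
    ggplot2::labs(x = "Spatial model weight w", y = "Mean CV AUC",
                  title = "Clinical/spatial probability fusion scan") +
    ggplot2::theme_minimal()
}

#' Plot a section's nuclear point pattern
#'
#' @param centroids Centroid table (`section_id`, `x`, `y`); all sections are
#'   faceted.
#' @param extent Optional `c(width, height)` to fix the panel limits.
#' @return A ggplot.
#' @export
plot_point_pattern <- function(centroids, extent = NULL) {
  p <- ggplot2::ggplot(centroids, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$section_id)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  if (!is.null(extent)) {
    p <- p + ggplot2::xlim(0, extent[1]) + ggplot2::ylim(0, extent[2])
  }
  p
}

#' Grade-group box plots of selected spatial features
#'
#' Box-and-jitter comparison of features between G1,2 and G3 sections, the
#' standard way univariately significant nuclear-architecture features are
#' reported.
#'
#' @param features Feature tibble from [extract_features()].
#' @param labels Binary section labels (1 = G3).
#' @param which Character vector of feature columns to show (default: the
#'   nuclear count).
#' @return A ggplot.
#' @export
plot_feature_comparison <- function(features, labels,
                                    which = "nuclei_count") {
  df <- features |>
    dplyr::select(dplyr::all_of(which)) |>
    dplyr::mutate(grade = factor(ifelse(as.integer(labels) == 1L, "G3", "G1,2"),
                                 levels = c("G1,2", "G3"))) |>
    tidyr::pivot_longer(-"grade", names_to = "feature", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grade, y = .data$value,
                                   fill = .data$grade)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 0.5, alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Feature value (a.u.)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
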