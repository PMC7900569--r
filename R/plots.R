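#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Box-and-whisker plot of laterality indices by band and region
#'
#' The standard display of group laterality: one panel per band, boxes per
#' region split by group, with the zero line (no asymmetry after baseline
#' correction) for reference.
#'
#' @param li Long laterality tibble with `group`, `band`, `region`, `li`.
#' @return A ggplot object.
#' @export
plot_li_distribution <- function(li) {
  ggplot2::ggplot(li, ggplot2::aes(x = .data$region, y = .data$li,
                                   fill = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(~band, nrow = 2) +
    ggplot2::labs(x = NULL, y = "laterality index", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.meg_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate (1 - specificity)",
      y = "true positive rate (sensitivity)",
      title = sprintf("ROC, positive = %s (AUC = %.3f)",
                      object$positive, object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.meg_loocv <- function(object, ...) {
  roc <- roc_curve(object$predictions$posterior, object$predictions$truth,
                   positive = object$positive)
  autoplot(roc, ...)
}

#' @export
autoplot.meg_source_image <- function(object, fm, ...) {
  d <- tibble::tibble(
    x = fm$source_locations[, 1], y = fm$source_locations[, 2],
    power = object$power, region = fm$region_labels
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  colour = .data$power,
                                  shape = .data$region)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Source power (%s band), axial view",
                                  object$band),
                  x = "x (left - right)", y = "y (posterior - anterior)") +
    ggplot2::theme_minimal()
}
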