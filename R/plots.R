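#' Scatter plot of subjects on the (occurrence, sparsity) plane
#'
#' @param assignment Tibble from [cluster_subjects()] (or
#'   [characterize_lesions()]; points are uncolored without a `subset`
#'   column).
#' @return A ggplot object.
#' @export
plot_subset_scatter <- function(assignment) {
  p <- ggplot2::ggplot(assignment,
                       ggplot2::aes(x = .data$occurrence,
                                    y = .data$sparsity))
  if ("subset" %in% names(assignment)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = factor(.data$subset)), alpha = 0.8) +
      ggplot2::labs(colour = "subset")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p + ggplot2::labs(x = "lesion occurrence", y = "lesion sparsity") +
    ggplot2::theme_minimal()
}

#' Boxplots of per-region estimation performance
#'
#' @param x A `lesion_evaluation` from [evaluate_pipeline()].
#' @param object,... Passed through by the autoplot generic.
#' @return A ggplot object.
#' @export
plot_region_performance <- function(x) {
  stopifnot(inherits(x, "lesion_evaluation"))
  long <- tidyr::pivot_longer(
    x$per_region,
    dplyr::all_of(c("accuracy", "specificity", "sensitivity")),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subset, y = .data$value,
                                     fill = .data$method)) +
    ggplot2::geom_boxplot(na.rm = TRUE) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "subset", y = "per-region value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.lesion_evaluation <- function(object, ...) {
  plot_region_performance(object)
}

#' Per-region coefficient of variation profile
#'
#' @param lesion_tbl Wide lesion table.
#' @param atlas Optional [region_atlas()] fixing region order.
#' @return A ggplot object.
#' @export
plot_region_cv <- function(lesion_tbl, atlas = NULL) {
  cv <- region_cv(lesion_tbl, atlas)
  cv$region <- factor(cv$region, levels = cv$region)
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$region, y = .data$cv)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "coefficient of variation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
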