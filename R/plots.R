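#' Plot group comparisons of network measures
#'
#' Box-and-jitter plot of each global measure by group, annotated with the
#' FDR-corrected q value.
#'
#' @param object A `tractnet_comparison` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tractnet_comparison <- function(object, ...) {
  vals <- attr(object, "subject_values")
  long <- tidyr::pivot_longer(vals, cols = -dplyr::any_of(c("subject_id",
                                                            "group")),
                              names_to = "measure", values_to = "value")
  labels <- dplyr::mutate(
    tibble::as_tibble(object),
    label = sprintf("q = %.3g", .data$q))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 1, alpha = 0.7) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(x = 1.5, y = Inf, label = .data$label),
                       vjust = 1.4, inherit.aes = FALSE, size = 3) +
    ggplot2::labs(x = NULL, y = "measure value",
                  title = "Global network measures by group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot measure-glucose partial correlations
#'
#' Scatter plots of each network measure against each glucose covariate
#' with a least-squares line, annotated with the partial r (confounds
#' controlled in the reported statistic, not removed from the axes).
#'
#' @param object A `tractnet_correlation` from [correlate_measures()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tractnet_correlation <- function(object, ...) {
  vals <- attr(object, "subject_values")
  measures <- unique(object$measure)
  covs <- unique(object$covariate)
  long <- tidyr::pivot_longer(vals, cols = dplyr::all_of(measures),
                              names_to = "measure", values_to = "value")
  long <- tidyr::pivot_longer(long, cols = dplyr::all_of(covs),
                              names_to = "covariate",
                              values_to = "glucose")
  labels <- dplyr::mutate(tibble::as_tibble(object),
                          label = sprintf("r = %.2f, q = %.3g",
                                          .data$r, .data$q))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$glucose,
                                          y = .data$value))
  if ("group" %in% names(long)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(shape = .data$group),
                                 size = 1.5, alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(size = 1.5, alpha = 0.8)
  }
  p +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_grid(measure ~ covariate, scales = "free") +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(x = -Inf, y = Inf, label = .data$label),
                       hjust = -0.05, vjust = 1.4, inherit.aes = FALSE,
                       size = 2.8) +
    ggplot2::labs(x = "glucose covariate", y = "network measure",
                  title = "Network measures vs glycemia") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
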