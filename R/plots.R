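# ggplot2 views of the result types. Figures mirror the standard
# presentation: metric-vs-age scatter with a linear trend per branch,
# grouped bars for the neonate/adult contrast, and distance-vs-age for
# the maturation index.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot metric age trends
#'
#' Scatter of L/R-averaged tract means against age with a linear trend,
#' faceted by bundle x metric.
#'
#' @param cohort tidy cohort table.
#' @param group group to plot.
#' @param metrics subset of metrics (default all present).
#' @return a ggplot.
#' @export
plot_trends <- function(cohort, group = "neonate", metrics = NULL) {
  d <- cohort_avg(cohort, group)
  if (!is.null(metrics)) d <- d[d$metric %in% metrics, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::facet_grid(metric ~ bundle, scales = "free_y") +
    ggplot2::labs(x = if (group == "neonate") "age (weeks PMA)" else
                    "age (years)",
                  y = "tract-mean value") +
    ggplot2::theme_minimal()
}

#' Plot the neonate-vs-adult group contrast
#'
#' Group means with SD error bars per bundle x metric.
#'
#' @param cohort tidy cohort table with both groups.
#' @return a ggplot.
#' @export
plot_group_contrast <- function(cohort) {
  d <- cohort_avg(cohort) |>
    dplyr::group_by(.data$group, .data$bundle, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bundle, y = .data$mean,
                                  fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           position = ggplot2::position_dodge(0.9),
                           width = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "tract mean", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a maturation result
#'
#' Mahalanobis distance against age per bundle, with linear trends — the
#' view in which less mature branches sit higher and all branches drift
#' downward (toward the adult reference) with age.
#'
#' @param object a `maturation_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.maturation_result <- function(object, ...) {
  ggplot2::ggplot(object$distances,
                  ggplot2::aes(x = .data$age, y = .data$m,
                               colour = .data$bundle)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "age (weeks PMA)", y = "Mahalanobis distance M",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.maturation_result
#' @param x a `maturation_result`.
#' @export
plot.maturation_result <- function(x, ...) print(autoplot(x, ...))
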