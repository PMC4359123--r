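#' Plot the distribution of per-replication reliability
#'
#' Histogram of the per-replication reliabilities (squared correlations) from
#' the replication engine, with the mean marked. Non-converged replications
#' are omitted.
#'
#' @param object An `olf_replication`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.olf_replication <- function(object, ...) {
  df <- dplyr::filter(object$per_rep, .data$converged)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reliability)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = mean(df$reliability), linetype = 2) +
    ggplot2::labs(
      x = expression(r^2 ~ "(estimated vs true thresholds)"),
      y = "replications",
      title = sprintf("Reliability over %d replications (%s)",
                      object$n_reps, object$estimator)
    ) +
    ggplot2::theme_minimal()
}

#' Bland-Altman agreement plot
#'
#' Differences between two paired sets of threshold estimates plotted against
#' the reference set, with a loess smoother — the standard display for
#' agreement between two measures of the same quantity.
#'
#' @param estimates_a,estimates_b Paired numeric vectors; `estimates_b` is
#'   the reference on the x axis.
#' @param label_a,label_b Axis labels.
#' @return A ggplot object.
#' @export
plot_agreement <- function(estimates_a, estimates_b,
                           label_a = "estimate A", label_b = "reference") {
  stopifnot(length(estimates_a) == length(estimates_b))
  df <- tibble(reference = estimates_b,
               difference = estimates_a - estimates_b)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = label_b,
                  y = sprintf("%s - %s", label_a, label_b)) +
    ggplot2::theme_minimal()
}

#' Plot a population threshold distribution
#'
#' Density of the true-threshold distribution on the dilution-step scale.
#'
#' @param object An `olf_population`.
#' @param from,to Plot range in step units (defaults cover mean +/- 4 SD).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.olf_population <- function(object, from = NULL, to = NULL, ...) {
  m <- mean_threshold(object)
  s <- sd_threshold(object)
  from <- from %||% (m - 4 * s)
  to <- to %||% (m + 4 * s)
  xs <- seq(from, to, length.out = 400)
  dens <- if (object$family == "normal") {
    stats::dnorm(xs, object$mean_t, object$sd_t)
  } else {
    stats::dgamma(pmax(xs - object$location, 0), shape = object$shape,
                  scale = object$scale)
  }
  ggplot2::ggplot(tibble(step = xs, density = dens),
                  ggplot2::aes(x = .data$step, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "threshold (dilution step)", y = "density") +
    ggplot2::theme_minimal()
}
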