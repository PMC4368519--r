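#' Rank-abundance plot of a sample
#'
#' @param object An [abundance_sample()].
#' @param ... Unused.
#' @return A ggplot: abundance (log scale) against rank.
#' @export
autoplot.abundance_sample <- function(object, ...) {
  df <- tibble::tibble(rank = seq_len(nrow(object)),
                       count = sort(object$count, decreasing = TRUE))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Species rank", y = "Abundance")
}

#' Null distribution of the bootstrap test statistic
#'
#' Histogram of the maximized log-likelihoods of the bootstrap null samples
#' with the observed sample's value marked; the p-value is the fraction of
#' the null mass to the left of the line.
#'
#' @param object A `neutrality_test` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.neutrality_test <- function(object, ...) {
  df <- tibble::tibble(logL = object$null_logL)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logL)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$fit$logL, colour = "red") +
    ggplot2::labs(x = "Maximized neutral log-likelihood (null samples)",
                  y = "Count",
                  subtitle = sprintf("p = %.3g", object$p_value))
}

#' Power curves from a sweep
#'
#' Plots power (with Jeffreys confidence intervals) against a chosen grid
#' variable, optionally coloured by a second one.
#'
#' @param object A `power_sweep` tibble.
#' @param x Name of the column for the horizontal axis (string).
#' @param colour Optional column name used for colour grouping.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_sweep <- function(object, x = "J", colour = NULL, ...) {
  aes <- ggplot2::aes(x = .data[[x]], y = .data$power,
                      ymin = .data$ci_low, ymax = .data$ci_high)
  p <- ggplot2::ggplot(object, aes)
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_pointrange(ggplot2::aes(colour = factor(.data[[colour]]))) +
      ggplot2::geom_line(ggplot2::aes(colour = factor(.data[[colour]]))) +
      ggplot2::labs(colour = colour)
  } else {
    p <- p + ggplot2::geom_pointrange() + ggplot2::geom_line()
  }
  p + ggplot2::scale_x_log10() +
    ggplot2::labs(y = "Power (rejection probability)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
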