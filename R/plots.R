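# ggplot2 displays for the main result types.

#' Plot a conditional quantile table
#'
#' Quantile fan of the conditioned member's phenotype against the
#' conditioning member's bin, one line per percentile.
#'
#' @param object A `gw_quantile_table`.
#' @param ref Optional second table (e.g. the reference) drawn as dashed
#'   black lines behind the object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gw_quantile_table <- function(object, ref = NULL, ...) {
  long <- function(qt) {
    tidyr::pivot_longer(as_tibble(qt), dplyr::all_of(quantile_cols),
                        names_to = "quantile", values_to = "value")
  }
  p <- ggplot2::ggplot(long(object),
                       ggplot2::aes(.data$bin_left, .data$value,
                                    colour = .data$quantile))
  if (!is.null(ref)) {
    p <- p + ggplot2::geom_line(data = long(ref), colour = "black",
                                linetype = "dashed",
                                ggplot2::aes(group = .data$quantile))
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "conditioning member's bin (left edge)",
                  y = "conditioned member's percentile",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a search result
#'
#' Candidate cost against the sum-of-gamma-p-n summary, showing the
#' meta-model restriction interval when present.
#'
#' @param object A `gw_search`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gw_search <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$sum_gpn, .data$mean_cost,
                                       colour = .data$stage)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(sum(gamma * p * n)), y = "mean cost",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(object$interval)) {
    p <- p + ggplot2::geom_vline(xintercept = object$interval,
                                 linetype = "dotted")
  }
  p
}

#' Plot power curves
#'
#' Detection power per locus against sample size, panelled by test.
#'
#' @param object A `gw_power`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gw_power <- function(object, ...) {
  ggplot2::ggplot(object$power,
                  ggplot2::aes(.data$n, .data$power, colour = .data$locus,
                               linetype = .data$kind)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~test) +
    ggplot2::labs(x = "sample size", y = "power at threshold",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}
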