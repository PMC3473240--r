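#' Pareto (CCDF) plot of a power-law fit
#'
#' Log-log plot of the empirical complementary CDF of the data with the
#' fitted power-law tail overlaid from the selected cutoff onward — the
#' standard visual check that the tail is straight and the fitted region
#' sensible.
#'
#' @param object A `pl_fit` from [fit_power_law()].
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pl_fit <- function(object, ...) {
  emp <- ccdf(object$values)
  tail_x <- emp$x[emp$x >= object$xmin]
  scale_at <- emp$p[match(min(tail_x), emp$x)]
  model <- tibble(
    x = tail_x,
    p = scale_at * hurwitz_zeta(object$beta_hat, tail_x) /
      hurwitz_zeta(object$beta_hat, object$xmin)
  )
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$x, y = .data$p)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = model, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "term frequency x", y = "P(X ≥ x)",
      title = sprintf("Power-law fit: beta = %.2f, xmin = %d",
                      object$beta_hat, as.integer(object$xmin))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Zipf rank-frequency plot
#'
#' @param freq_table Frequency table from [term_frequencies()].
#' @return A ggplot object (log-log rank vs frequency).
#' @export
plot_rank_frequency <- function(freq_table) {
  rf <- rank_frequency(freq_table)
  ggplot2::ggplot(rf, ggplot2::aes(x = .data$rank, y = .data$frequency)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Exponent versus corpus size scatter
#'
#' @param association Result of [size_exponent_association()].
#' @return A ggplot object (beta against distinct-term count, log x).
#' @export
plot_size_exponent <- function(association) {
  ggplot2::ggplot(association$data,
                  ggplot2::aes(x = .data$n_distinct, y = .data$beta)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "distinct GO identifiers", y = "power-law exponent β") +
    ggplot2::theme_minimal()
}
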