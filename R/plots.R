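# ggplot2 views of the analytic series.

#' Plot female-only / male-only / mixed yearly proportions
#'
#' @param series Tibble from [sex_series()].
#' @return A ggplot object.
#' @export
plot_sex_series <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$year, y = .data$pct,
                                       colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "publication year", y = "% of sex-reporting abstracts",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot yearly offender-category rates
#'
#' @param series Tibble from [offender_rates()].
#' @return A ggplot object.
#' @export
plot_offender_rates <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$year, y = .data$pct,
                                       colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "publication year",
                  y = "% of offender-type-reporting abstracts",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the age-group distribution
#'
#' @param dist Tibble from [age_distribution()].
#' @return A ggplot object.
#' @export
plot_age_distribution <- function(dist) {
  dist$group <- factor(dist$group, levels = age_groups()$group)
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$group, y = .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of age-reporting abstracts") +
    ggplot2::theme_minimal()
}
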