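#' Plot an allometric fit over its calibration data
#'
#' Log10-log10 scatter of a trait table with the fitted line.
#'
#' @param fit An `allometric_fit`.
#' @param data The trait table (`taxon`, `x`, `y`) the fit was made on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.allometric_fit <- function(fit, data, ...) {
  stopifnot(is.data.frame(data), all(c("x", "y") %in% names(data)))
  ggplot2::ggplot(data, ggplot2::aes(x = log10(.data$x), y = log10(.data$y))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         colour = "firebrick") +
    ggplot2::labs(
      x = paste0("log10 ", fit$predictor),
      y = paste0("log10 ", fit$response),
      title = sprintf("%s fit: slope %.3f, intercept %.3f%s",
                      fit$method, fit$slope, fit$intercept,
                      if (is.na(fit$lambda)) "" else
                        sprintf(", lambda %.3g", fit$lambda))
    ) +
    ggplot2::theme_minimal()
}

#' EQ, brain mass and body mass through time
#'
#' Scatter of log10 EQ (both scalings), log10 brain mass and log10 body mass
#' against geological age for a table of fossil estimates, faceted by
#' quantity. Age increases leftward (toward the past).
#'
#' @param estimates A `fossil_estimates` tibble with `age_ma` populated.
#' @return A ggplot object.
#' @export
plot_eq_timeline <- function(estimates) {
  stopifnot(is.data.frame(estimates), "age_ma" %in% names(estimates))
  long <- estimates |>
    dplyr::transmute(
      taxon = .data$taxon, age_ma = .data$age_ma,
      `log10 EQ (0.56)` = .data$log10_EQ_0.56,
      `log10 EQ (0.75)` = .data$log10_EQ_0.75,
      `log10 brain mass (g)` = log10(.data$brain_mass_g),
      `log10 body mass (kg)` = log10(.data$body_mass_kg)
    ) |>
    tidyr::pivot_longer(-c("taxon", "age_ma"), names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age_ma, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Age (Ma)", y = NULL) +
    ggplot2::theme_minimal()
}
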