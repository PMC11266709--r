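#' Plot nonzero-proportion stability profiles
#'
#' One bar per design column showing the proportion of replicates with a
#' nonzero coefficient, with the retention threshold marked; essential
#' terms are highlighted.
#'
#' @param object An `enet_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.enet_selection <- function(object, ...) {
  d <- dplyr::mutate(object$summary,
                     status = dplyr::case_when(
                       .data$essential ~ "essential",
                       .data$retained ~ "retained",
                       TRUE ~ "dropped"))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$prop_nonzero,
    y = stats::reorder(.data$term, .data$prop_nonzero),
    fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "proportion of replicates with nonzero coefficient",
                  y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cross-validated error distributions
#'
#' Boxplots of the per-run mean squared errors for each evaluated model
#' and the null model.
#'
#' @param object A `cv_evaluation`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$runs,
                  ggplot2::aes(x = .data$model, y = .data$mse)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "per-run CV mean squared error") +
    ggplot2::theme_minimal()
}

#' Plot an adjusted-effect curve
#'
#' Fitted outcome against the focal predictor with other covariates at
#' their means, one curve per treatment arm, band = fit plus/minus one
#' standard error.
#'
#' @param object An `adjusted_effect` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.adjusted_effect <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$fit))
  if (!all(is.na(object$group))) {
    p <- p + ggplot2::aes(colour = .data$group, fill = .data$group)
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = object$focal[1], y = "adjusted outcome (standardized)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot final-model coefficients
#'
#' Point-range display of the unpenalized coefficient estimates with one
#' standard error either side.
#'
#' @param object A `final_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.final_model <- function(object, ...) {
  d <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$estimate,
    y = stats::reorder(.data$term, abs(.data$estimate)))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - .data$std.error,
      xmax = .data$estimate + .data$std.error)) +
    ggplot2::labs(x = "coefficient (standardized outcome)", y = NULL) +
    ggplot2::theme_minimal()
}
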