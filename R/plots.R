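#' Correlation plot of calculated vs experimental free energies
#'
#' Scatter of calculated against experimental values with the identity line
#' and shaded +/- 1 and +/- 2 kcal/mol accuracy bands, the standard visual
#' for RBFE benchmark results.
#'
#' @param data edge tibble or [perturbation_network()].
#' @param calc,exp column names.
#' @param sigma optional uncertainty column for error bars.
#' @return a ggplot object.
#' @export
plot_correlation <- function(data, calc = "ddg_calc", exp = "ddg_exp",
                             sigma = "sigma_calc") {
  if (inherits(data, "perturbation_network")) data <- data$edges
  data <- as_tibble(data)
  rng <- range(c(data[[calc]], data[[exp]]), na.rm = TRUE) + c(-1, 1)
  band <- tibble(x = rng)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data[[exp]], y = .data[[calc]])) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$x, ymin = .data$x - 2,
                                      ymax = .data$x + 2),
                         inherit.aes = FALSE, fill = "grey85") +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$x, ymin = .data$x - 1,
                                      ymax = .data$x + 1),
                         inherit.aes = FALSE, fill = "grey70") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 2)
  if (!is.null(sigma) && sigma %in% names(data)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data[[calc]] - .data[[sigma]],
                   ymax = .data[[calc]] + .data[[sigma]]), width = 0)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "experimental (kcal/mol)", y = "calculated (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' @method autoplot atm_node_estimates
#' @export
autoplot.atm_node_estimates <- function(object, ...) {
  plot_correlation(as_tibble(object), calc = "dg", exp = "dg_exp",
                   sigma = "sigma") +
    ggplot2::labs(x = "experimental dG (kcal/mol)",
                  y = "estimated dG (kcal/mol)")
}

#' @method autoplot fe_result
#' @export
autoplot.fe_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$lambda, y = .data$f)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(lambda), y = "reduced free energy f") +
    ggplot2::theme_minimal()
}

#' @method autoplot method_comparison
#' @export
autoplot.method_comparison <- function(object, ...) {
  long <- tibble(
    method = rep(object$method, 3),
    statistic = rep(c("Kendall tau", "MAE", "RMSE"), each = nrow(object)),
    value = c(object$tau, object$mae, object$rmse),
    sigma = c(object$tau_sigma, object$mae_sigma, object$rmse_sigma))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$sigma,
                                        ymax = .data$value + .data$sigma),
                           width = 0.2) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::theme_minimal()
}
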