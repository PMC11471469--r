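#' Plot a fitted lifetime model over the sample
#'
#' Overlays the fitted density on a density-scaled histogram of the data.
#'
#' @param object a [fit_dus()] result.
#' @param bins number of histogram bins.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dus_fit <- function(object, bins = 12, ...) {
  df <- tibble::tibble(value = object$data)
  grid <- seq(0, max(object$data) * 1.1, length.out = 400)
  dens <- switch(object$model,
    dus_lindley = ddus(grid, object$estimate),
    lindley = dlindley(grid, object$estimate),
    dus_exponential = ddus(grid, object$estimate, base = "exponential"),
    exponential = object$estimate * exp(-object$estimate * grid))
  fit_df <- tibble::tibble(value = grid, density = dens)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80",
                            colour = "grey40") +
    ggplot2::geom_line(data = fit_df,
                       ggplot2::aes(x = .data$value, y = .data$density),
                       colour = "#2c7fb8", linewidth = 1) +
    ggplot2::labs(x = "lifetime", y = "density",
                  title = sprintf("%s fit (%s), xi = %.4f", object$model,
                                  toupper(object$method),
                                  object$estimate)) +
    ggplot2::theme_minimal()
}

#' Plot a Monte-Carlo estimator study
#'
#' Mean squared error of the MLE against sample size, one line per true
#' parameter value, on log-log axes.
#'
#' @param object a [run_mc_study()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dus_mc_study <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n, y = .data$mse,
                               colour = factor(.data$xi_true),
                               group = factor(.data$xi_true))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sample size n", y = "MSE of the MLE",
                  colour = expression(xi)) +
    ggplot2::theme_minimal()
}

#' Plot the DUS Lindley density, CDF, survival and hazard curves
#'
#' @param xi one or more shape parameter values (one curve per value).
#' @param upper right end of the time grid; defaults to the 99.5\%
#'   quantile of the widest curve.
#' @return a ggplot object, facetted by curve type.
#' @export
plot_dus_curves <- function(xi, upper = NULL) {
  check_xi(xi)
  if (is.null(upper)) upper <- max(qdus(0.995, min(xi)), qdus(0.995, max(xi)))
  grid <- seq(0, upper, length.out = 300)
  pieces <- lapply(xi, function(v) {
    rb <- dus_reliability(grid, v)
    tibble::tibble(
      z = rep(grid, 4),
      value = c(rb$density, rb$cdf, rb$survival, rb$hazard),
      curve = rep(c("density", "CDF", "survival", "hazard"),
                  each = length(grid)),
      xi = v)
  })
  df <- dplyr::bind_rows(pieces)
  df$curve <- factor(df$curve, levels = c("density", "CDF", "survival",
                                          "hazard"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$value,
                                   colour = factor(.data$xi))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free_y") +
    ggplot2::labs(x = "z", y = NULL, colour = expression(xi)) +
    ggplot2::theme_minimal()
}
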