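# broom-style accessors and ggplot2 autoplot methods for the result classes

#' Tidy a fitted Gaussian mixture
#'
#' @param x A `vlp_gmm` fit.
#' @param conf_int Append Student-t confidence intervals for the component
#'   means (see [component_ci()])?
#' @param confidence Confidence level used when `conf_int = TRUE`.
#' @param ... Unused.
#' @return A tibble with one row per component: `component`, `weight`,
#'   `mean`, `sigma`, and interval columns when requested.
#' @method tidy vlp_gmm
#' @export
tidy.vlp_gmm <- function(x, conf_int = FALSE, confidence = 0.95, ...) {
  out <- dplyr::bind_cols(tibble(component = seq_len(x$k)), x$components)
  if (conf_int) {
    ci <- component_ci(x, confidence = confidence)
    out <- dplyr::left_join(out, ci[, c("component", "half_width", "lower", "upper")],
                            by = "component")
  }
  out
}

#' One-row summary of a fitted Gaussian mixture
#'
#' @param x A `vlp_gmm` fit.
#' @param ... Unused.
#' @return A tibble with `k`, `n_parameters` (3k - 1), `n`, `loglik`,
#'   `n_iter`, `converged`, `unit`, `condition`.
#' @method glance vlp_gmm
#' @export
glance.vlp_gmm <- function(x, ...) {
  tibble(k = x$k, n_parameters = 3L * x$k - 1L, n = x$n, loglik = x$loglik,
         n_iter = x$n_iter, converged = x$converged, unit = x$unit,
         condition = x$condition)
}

#' @method tidy vlp_qq
#' @export
tidy.vlp_qq <- function(x, ...) x$points

#' @method glance vlp_qq
#' @export
glance.vlp_qq <- function(x, ...) {
  tibble(n = x$n, slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared)
}

#' @method tidy vlp_gmm_selection
#' @export
tidy.vlp_gmm_selection <- function(x, ...) x$report

#' @method glance vlp_gmm_selection
#' @export
glance.vlp_gmm_selection <- function(x, ...) {
  dplyr::bind_cols(tibble(k_selected = x$k), glance(x$model)[-1])
}

#' Plot a fitted mixture over the measurement histogram
#'
#' @param object A `vlp_gmm` fit (with stored data).
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object: density-scaled histogram, weighted component
#'   densities, and the total mixture density.
#' @method autoplot vlp_gmm
#' @export
autoplot.vlp_gmm <- function(object, bins = 30, ...) {
  if (is.null(object$data)) {
    vlp_abort("Fit was created with `keep_data = FALSE`; nothing to plot.")
  }
  x <- object$data
  grid <- seq(min(x) - 2 * sd(x), max(x) + 2 * sd(x), length.out = 400)
  comp <- tidy(object)
  dens <- purrr::map_dfr(seq_len(nrow(comp)), function(k) {
    tibble(x = grid,
           density = comp$weight[k] * gaussian_pdf(grid, comp$mean[k], comp$sigma[k]),
           component = factor(k))
  })
  mix <- tibble(x = grid, density = mixture_pdf(grid, object))
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble(x = x),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(x = .data$x, y = .data$density, colour = .data$component),
      linewidth = 0.6) +
    ggplot2::geom_line(
      data = mix,
      ggplot2::aes(x = .data$x, y = .data$density),
      linewidth = 0.9) +
    ggplot2::labs(
      x = object$unit %||% "value", y = "density",
      colour = "component",
      title = sprintf("%d-component Gaussian mixture", object$k)) +
    ggplot2::theme_minimal()
}

#' Plot a mixture quantile-quantile diagnostic
#'
#' The red line is the identity: perfect, noiseless agreement between data
#' and model.
#'
#' @param object A `vlp_qq` diagnostic.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vlp_qq
#' @export
autoplot.vlp_qq <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$theoretical, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "theoretical mixture quantile", y = "observed quantile",
      title = sprintf("Mixture QQ plot (R² = %.4f)", object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a model-selection report
#'
#' @param object A `vlp_gmm_selection` result.
#' @param ... Unused.
#' @return A ggplot object showing log-likelihood and QQ linearity per
#'   candidate component count.
#' @method autoplot vlp_gmm_selection
#' @export
autoplot.vlp_gmm_selection <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$report[, c("k", "loglik", "qq_r_squared")],
    cols = c("loglik", "qq_r_squared"),
    names_to = "criterion", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = dplyr::mutate(long, chosen = .data$k == object$k),
      ggplot2::aes(colour = .data$chosen)) +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "number of components", y = NULL, colour = "selected") +
    ggplot2::theme_minimal()
}
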