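#' Plot posterior smooth-effect curves
#'
#' One panel per smooth term: posterior mean with shaded 95% (outer) and
#' 80% (inner) pointwise credible bands.
#'
#' @param object A `geowaz_fit`.
#' @param ... Passed to [smooth_effects()].
#' @return A ggplot object.
#' @method autoplot geowaz_fit
#' @export
autoplot.geowaz_fit <- function(object, ...) {
  eff <- smooth_effects(object, ...)
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5),
                         fill = "grey80") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q10, ymax = .data$q90),
                         fill = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linewidth = 0.7) +
    ggplot2::facet_wrap(~ term, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "partial effect on WAZ",
                  title = "Non-linear covariate effects (80/95% credible bands)")
}

#' Plot the per-region spatial effect with significance classes
#'
#' @param fit A `geowaz_fit` with a spatial term.
#' @return A ggplot object (regions on the x axis, posterior mean and 95%
#'   interval, coloured by significance class).
#' @export
plot_spatial_effect <- function(fit) {
  surf <- spatial_effect_surface(fit)
  ggplot2::ggplot(surf, ggplot2::aes(x = .data$region, y = .data$mean,
                                     colour = .data$significance)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q2.5,
                                          ymax = .data$q97.5)) +
    ggplot2::scale_colour_manual(values = c(positive = "#b2182b",
                                            negative = "#2166ac",
                                            null = "grey55")) +
    ggplot2::labs(y = "spatial effect on WAZ (centred)", x = NULL,
                  title = "Structured spatial effect, 95% credible intervals")
}

#' Plot an IDW-interpolated severity surface with hotspots
#'
#' @param grid A classified grid from [hotspot_classify()] (or a
#'   `geowaz_idw` tibble, in which case hotspots are not outlined).
#' @return A ggplot object.
#' @export
plot_idw <- function(grid) {
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_viridis_c(name = "predicted\nseverity") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "IDW-interpolated predicted underweight severity")
  if ("hotspot" %in% names(grid)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(grid, .data$hotspot),
      shape = ".", colour = "yellow")
  }
  p
}

#' Residual and scale-location diagnostic panels
#'
#' @param fit A `geowaz_fit`.
#' @return A ggplot object with two facets: residuals vs fitted, and
#'   scale-location.
#' @export
plot_diagnostics <- function(fit) {
  d <- residual_diagnostics(fit)
  long <- dplyr::bind_rows(
    tibble::tibble(panel = "Residuals vs fitted", x = d$fitted, y = d$residual),
    tibble::tibble(panel = "Scale-location", x = d$fitted, y = d$sqrt_abs_std))
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "#b2182b", linewidth = 0.6) +
    ggplot2::facet_wrap(~ panel, scales = "free_y") +
    ggplot2::labs(x = "fitted values", y = NULL)
}

#' Plot the per-lag maximum autocorrelation
#'
#' @param fit A `geowaz_fit`.
#' @param lags Maximum lag.
#' @return A ggplot object.
#' @export
plot_max_acf <- function(fit, lags = 20) {
  ac <- max_autocorrelation(fit, lags = lags)
  ggplot2::ggplot(ac, ggplot2::aes(.data$lag, .data$max_acf)) +
    ggplot2::geom_col(width = 0.15) +
    ggplot2::labs(y = "max autocorrelation over parameters",
                  title = "Maximum autocorrelation of all model parameters")
}

#' Plot a binned covariate-response screening profile
#'
#' @param profile A tibble from [binned_profile()].
#' @return A ggplot object.
#' @export
plot_binned_profile <- function(profile) {
  ggplot2::ggplot(dplyr::filter(profile, .data$count > 0),
                  ggplot2::aes(.data$center, .data$mean_y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$count), alpha = 0.7) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(x = "covariate bin centre", y = "mean response")
}
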