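#' Posterior summary of a draw matrix
#'
#' Summarizes each column of a matrix of MCMC draws with the empirical
#' mean, SD and quantiles (linear interpolation of order statistics,
#' `type = 7`), plus a credible-interval significance flag: `"positive"` if
#' the lower 95% bound exceeds zero, `"negative"` if the upper bound is
#' below zero, `"null"` otherwise.
#'
#' @param draws Numeric matrix (draws x parameters) or vector; at least two
#'   draws.
#' @param probs Quantile levels; must include 0.025 and 0.975 for the
#'   significance flag. Defaults add the 10/90% levels used for 80% bands.
#' @param min_max Also report the min and max across draws (the layout used
#'   for smoothing-variance tables).
#' @return A tibble with one row per parameter: `term`, `mean`, `sd`,
#'   quantile columns (`q2.5`, ...), optional `min`/`max`, `significance`.
#' @export
posterior_summary <- function(draws, probs = c(0.025, 0.1, 0.5, 0.9, 0.975),
                              min_max = FALSE) {
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1)
  if (nrow(draws) < 2) {
    stop_geowaz("Need at least two retained draws to summarize.", "validation")
  }
  probs <- sort(unique(probs))
  qs <- t(apply(draws, 2, quantile, probs = probs, type = 7, names = FALSE))
  colnames(qs) <- quantile_labels(probs)
  out <- tibble::tibble(
    term = colnames(draws) %||% paste0("par", seq_len(ncol(draws))),
    mean = colMeans(draws),
    sd = apply(draws, 2, sd)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(qs))
  if (min_max) {
    out$min <- apply(draws, 2, min)
    out$max <- apply(draws, 2, max)
  }
  if (all(c("q2.5", "q97.5") %in% names(out))) {
    out$significance <- flag_significance(out)
  }
  out
}

#' Credible-interval significance flag
#'
#' A parameter is flagged significant at the 95% level when its equal-tailed
#' 95% credible interval excludes zero: `"positive"` when the 2.5% quantile
#' is above zero, `"negative"` when the 97.5% quantile is below zero, and
#' `"null"` otherwise.
#'
#' @param summary A data frame with columns `q2.5` and `q97.5` (or a
#'   two-column matrix of lower/upper bounds).
#' @return Character vector in `{"positive", "negative", "null"}`.
#' @export
flag_significance <- function(summary) {
  if (is.matrix(summary)) {
    lo <- summary[, 1]; hi <- summary[, 2]
  } else {
    lo <- summary$q2.5; hi <- summary$q97.5
  }
  dplyr::case_when(lo > 0 ~ "positive", hi < 0 ~ "negative", TRUE ~ "null")
}

#' Tidy posterior tables from a geoadditive fit
#'
#' Returns the model's posterior summary tables as tibbles in the layout
#' conventional for structured additive regression output: fixed effects
#' (`effect = "fixed"`) with mean, SD and 2.5/50/97.5% quantiles per
#' dummy-coded coefficient; smoothing-variance rows (`"smooth_variance"`,
#' labelled `sx(<term>)`, with min/max across draws); the error variance
#' (`"scale"`); or per-region spatial effects (`"spatial"`).
#'
#' @param x A `geowaz_fit`.
#' @param effect One of `"fixed"`, `"smooth_variance"`, `"scale"`,
#'   `"spatial"`.
#' @param ... Unused.
#' @return A tibble (see [posterior_summary()] for columns).
#' @method tidy geowaz_fit
#' @export
tidy.geowaz_fit <- function(x, effect = c("fixed", "smooth_variance",
                                          "scale", "spatial"), ...) {
  effect <- match.arg(effect)
  probs <- c(0.025, 0.5, 0.975)
  switch(effect,
    fixed = posterior_summary(x$gamma, probs = probs),
    smooth_variance = {
      draws <- x$tau2
      colnames(draws) <- paste0("sx(", colnames(draws), ")")
      posterior_summary(draws, probs = probs, min_max = TRUE)
    },
    scale = posterior_summary(matrix(x$sigma2, ncol = 1,
                                     dimnames = list(NULL, "Sigma2")),
                              probs = probs),
    spatial = {
      if (is.null(x$fspat)) {
        stop_geowaz("Model has no spatial term.", "validation")
      }
      dplyr::rename(posterior_summary(x$fspat), region = "term")
    }
  )
}

#' One-row model summary
#'
#' @param x A `geowaz_fit`.
#' @param ... Unused.
#' @return A tibble with `n`, `n_draws`, posterior mean error variance
#'   `sigma2`, `dic`, `p_d`, and `dbar`.
#' @method glance geowaz_fit
#' @export
glance.geowaz_fit <- function(x, ...) {
  ic <- compute_dic(x)
  tibble::tibble(n = x$n, n_draws = x$n_draws, sigma2 = mean(x$sigma2),
                 dic = ic$dic, p_d = ic$p_d, dbar = ic$dbar)
}

#' @export
summary.geowaz_fit <- function(object, ...) {
  out <- list(fixed = tidy(object, "fixed"),
              smooth_variance = tidy(object, "smooth_variance"),
              scale = tidy(object, "scale"),
              glance = glance(object))
  class(out) <- "summary.geowaz_fit"
  out
}

#' @export
print.summary.geowaz_fit <- function(x, ...) {
  cat("Estimates of fixed effects, parametric coefficients\n")
  print(as.data.frame(x$fixed), digits = 4)
  cat("\nSmooth term variances\n")
  print(as.data.frame(x$smooth_variance), digits = 4)
  cat("\nScale estimate\n")
  print(as.data.frame(x$scale), digits = 4)
  cat(sprintf("\nDIC = %.2f (pD = %.2f)\n", x$glance$dic, x$glance$p_d))
  invisible(x)
}

#' Posterior smooth-effect curves with credible bands
#'
#' Evaluates each P-spline smooth on a covariate grid for every retained
#' draw and summarizes pointwise: posterior mean and 80% and 95% credible
#' bands, the display conventionally used for non-linear covariate effects.
#'
#' @param fit A `geowaz_fit`.
#' @param terms Smooth term names (default all).
#' @param n_grid Number of grid points per term.
#' @return A tibble: `term`, `x`, `mean`, `q2.5`, `q10`, `q50`, `q90`,
#'   `q97.5`.
#' @export
smooth_effects <- function(fit, terms = NULL, n_grid = 100) {
  terms <- terms %||% names(fit$design$smooths)
  purrr::map_dfr(terms, function(nm) {
    sm <- fit$design$smooths[[nm]]
    if (is.null(sm)) stop_geowaz(sprintf("No smooth term `%s`.", nm), "validation")
    grid <- seq(sm$range[1], sm$range[2], length.out = n_grid)
    Bg <- splines::splineDesign(sm$knots, grid, ord = sm$degree + 1)
    curves <- fit$beta[[nm]] %*% t(Bg)         # draws x grid
    qs <- apply(curves, 2, quantile,
                probs = c(0.025, 0.1, 0.5, 0.9, 0.975), type = 7, names = FALSE)
    tibble::tibble(term = nm, x = grid, mean = colMeans(curves),
                   q2.5 = qs[1, ], q10 = qs[2, ], q50 = qs[3, ],
                   q90 = qs[4, ], q97.5 = qs[5, ])
  })
}
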