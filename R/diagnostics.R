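#' Deviance information criterion for a geoadditive fit
#'
#' Computes the Gaussian deviance `D(theta) = n log(2 pi sigma2) +
#' sum((y - eta)^2) / sigma2` per retained draw, its posterior mean `Dbar`,
#' the deviance at the posterior means `D(theta_bar)` (posterior-mean linear
#' predictor and posterior-mean error variance), the effective number of
#' parameters `pD = Dbar - D(theta_bar)` and `DIC = Dbar + pD`. `pD` can be
#' negative in pathological cases and is then reported as-is with a
#' warning.
#'
#' @param fit A `geowaz_fit`.
#' @return A list of class `geowaz_dic`: `dbar`, `d_hat`, `p_d`, `dic`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "geowaz_fit"))
  dbar <- mean(fit$deviance)
  sig_bar <- mean(fit$sigma2)
  ssr_hat <- sum((fit$design$y - fit$eta_bar)^2)
  d_hat <- fit$n * log(2 * pi * sig_bar) + ssr_hat / sig_bar
  p_d <- dbar - d_hat
  if (is.finite(p_d) && p_d < 0) {
    rlang::warn("Negative effective number of parameters (pD); reported as-is.")
  }
  structure(list(dbar = dbar, d_hat = d_hat, p_d = p_d, dic = dbar + p_d),
            class = "geowaz_dic")
}

#' @export
print.geowaz_dic <- function(x, ...) {
  cat(sprintf("DIC = %.2f  (Dbar = %.2f, D(theta_bar) = %.2f, pD = %.2f)\n",
              x$dic, x$dbar, x$d_hat, x$p_d))
  invisible(x)
}

#' Maximum autocorrelation across model parameters
#'
#' Computes the sample autocorrelation of every retained scalar parameter
#' chain (fixed effects, spline coefficients, spatial effects, smoothing
#' variances, error variance) and reports, per lag, the maximum across
#' parameters — a single-figure mixing diagnostic for the whole model.
#'
#' @param fit A `geowaz_fit`, or a plain numeric matrix of draws
#'   (iterations x parameters).
#' @param lags Maximum lag (default 20).
#' @return A tibble `lag`, `max_acf` (lag 0 is exactly 1).
#' @export
max_autocorrelation <- function(fit, lags = 20) {
  lags <- check_scalar_count(lags, "lags", min = 1L)
  chains <- if (inherits(fit, "geowaz_fit")) {
    cbind(fit$gamma, do.call(cbind, fit$beta), fit$fspat,
          fit$tau2, sigma2 = fit$sigma2)
  } else {
    as.matrix(fit)
  }
  if (nrow(chains) <= lags) {
    stop_geowaz("Chain shorter than the requested maximum lag.", "validation")
  }
  keep <- apply(chains, 2, function(v) sd(v) > 0)
  ac <- apply(chains[, keep, drop = FALSE], 2, function(v) {
    drop(acf(v, lag.max = lags, plot = FALSE)$acf)
  })
  tibble::tibble(lag = 0:lags, max_acf = apply(ac, 1, max))
}

#' Residual and scale-location diagnostics
#'
#' Residuals are `y - eta_bar` with `eta_bar` the posterior-mean linear
#' predictor; standardized residuals divide by the posterior-mean error SD.
#' The scale-location pairs are `(eta_bar, sqrt(|standardized residual|))`.
#' Both should be patternless under a correctly specified model.
#'
#' @param fit A `geowaz_fit`.
#' @return A tibble: `fitted`, `residual`, `std_residual`, `sqrt_abs_std`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "geowaz_fit"))
  r <- fit$design$y - fit$eta_bar
  s <- sqrt(mean(fit$sigma2))
  tibble::tibble(fitted = fit$eta_bar, residual = r, std_residual = r / s,
                 sqrt_abs_std = sqrt(abs(r / s)))
}

#' Stepwise term selection by DIC
#'
#' Greedy forward-backward search over candidate model terms, scoring each
#' visited model by its DIC from a full Gibbs fit. Starting from the base
#' model (intercept plus `fixed`), the forward phase adds the candidate
#' whose inclusion lowers DIC most; the backward phase drops any included
#' candidate whose removal lowers DIC; phases alternate until no move
#' improves. Ties keep the smaller model. Deterministic given `control$seed`
#' (each visited model gets a seed derived from the master seed and its
#' visit index).
#'
#' @param data Data frame of records.
#' @param response Response column name.
#' @param fixed Always-included fixed-effect columns.
#' @param candidates A list of candidate terms; each element is
#'   `list(type = "smooth", term = <col>)`,
#'   `list(type = "fixed", term = <col>)`, or
#'   `list(type = "spatial", term = <col>)` (needs `adjacency`). A bare
#'   character vector is taken as smooth candidates.
#' @param adjacency Edge list for a spatial candidate.
#' @param priors,control Passed to [fit_geoadditive()].
#' @return A list of class `geowaz_stepwise`: `selected` (list of retained
#'   candidate terms), `fit` (final refit), `trace` (tibble of every model
#'   visited: step, action, term, dic, kept).
#' @export
stepwise_select <- function(data, response, fixed = character(),
                            candidates, adjacency = NULL,
                            priors = prior_control(),
                            control = mcmc_control()) {
  if (is.character(candidates)) {
    candidates <- purrr::map(candidates, ~ list(type = "smooth", term = .x))
  }
  if (length(candidates) < 1) {
    stop_geowaz("Need at least one candidate term.", "validation")
  }
  cand_names <- vapply(candidates, `[[`, character(1), "term")
  names(candidates) <- cand_names

  visit <- 0L
  fit_subset <- function(included) {
    visit <<- visit + 1L
    sel <- candidates[included]
    types <- vapply(sel, `[[`, character(1), "type")
    fx <- c(fixed, cand_names[included][types == "fixed"])
    sm <- cand_names[included][types == "smooth"]
    sp <- cand_names[included][types == "spatial"]
    ctl <- control
    ctl$seed <- (control$seed + 7907L * visit) %% .Machine$integer.max
    fit <- fit_geoadditive(data, response = response, fixed = fx, smooth = sm,
                           spatial = if (length(sp)) sp[1] else NULL,
                           adjacency = adjacency, priors = priors,
                           control = ctl)
    list(fit = fit, dic = compute_dic(fit)$dic)
  }

  included <- rep(FALSE, length(candidates))
  current <- fit_subset(included)
  trace <- tibble::tibble(step = 0L, action = "start", term = NA_character_,
                          dic = current$dic, accepted = TRUE)
  step <- 0L
  repeat {
    improved <- FALSE
    # forward
    for (i in which(!included)) {
      step <- step + 1L
      trial <- fit_subset(replace(included, i, TRUE))
      accept <- trial$dic < current$dic    # tie keeps the smaller model
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        step = step, action = "add", term = cand_names[i],
        dic = trial$dic, accepted = accept))
      if (accept) {
        included[i] <- TRUE
        current <- trial
        improved <- TRUE
      }
    }
    # backward
    for (i in which(included)) {
      step <- step + 1L
      trial <- fit_subset(replace(included, i, FALSE))
      accept <- trial$dic <= current$dic   # tie drops: smaller model wins
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        step = step, action = "drop", term = cand_names[i],
        dic = trial$dic, accepted = accept))
      if (accept) {
        included[i] <- FALSE
        current <- trial
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  structure(list(selected = candidates[included], fit = current$fit,
                 dic = current$dic, trace = trace),
            class = "geowaz_stepwise")
}

#' @export
print.geowaz_stepwise <- function(x, ...) {
  cat(sprintf("Stepwise DIC selection: %d term(s) retained (final DIC %.2f)\n",
              length(x$selected), x$dic))
  if (length(x$selected) > 0) {
    cat(" ", paste(vapply(x$selected, `[[`, character(1), "term"),
                   collapse = ", "), "\n")
  }
  invisible(x)
}
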