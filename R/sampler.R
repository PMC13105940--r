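#' Hyperprior and MCMC control settings
#'
#' `prior_control()` sets the inverse-gamma hyperpriors: one `(a, b)` pair
#' shared by all smoothing variances (overridable per term via `terms`) and
#' one for the error variance. The default `a = b = 0.001` is the
#' conventional weakly-informative choice for variance parameters in
#' structured additive regression.
#'
#' @param a,b Shape and scale for every smoothing variance.
#' @param a_sigma,b_sigma Shape and scale for the error variance.
#' @param terms Optional named list of per-term `list(a =, b =)` overrides.
#' @return A list of class `geowaz_priors`.
#' @export
prior_control <- function(a = 0.001, b = 0.001, a_sigma = 0.001,
                          b_sigma = 0.001, terms = list()) {
  for (v in c(a, b, a_sigma, b_sigma, unlist(terms))) {
    if (!is.finite(v) || v <= 0) {
      stop_geowaz("All prior shapes and scales must be strictly positive.",
                  "validation")
    }
  }
  structure(list(a = a, b = b, a_sigma = a_sigma, b_sigma = b_sigma,
                 terms = terms), class = "geowaz_priors")
}

#' @param iterations Total Gibbs iterations.
#' @param burnin Burn-in iterations discarded from the front
#'   (`burnin < iterations`).
#' @param thin Thinning interval (keep every `thin`-th post-burn-in draw).
#' @param seed Integer RNG seed; every run is bit-reproducible given the
#'   seed.
#' @rdname prior_control
#' @export
mcmc_control <- function(iterations = 12000, burnin = 2000, thin = 10,
                         seed = 1L) {
  iterations <- check_scalar_count(iterations, "iterations")
  burnin <- check_scalar_count(burnin, "burnin", min = 0L)
  thin <- check_scalar_count(thin, "thin")
  if (burnin >= iterations) {
    stop_geowaz("`burnin` must be smaller than `iterations`.", "validation")
  }
  structure(list(iterations = iterations, burnin = burnin, thin = thin,
                 seed = as.integer(seed)), class = "geowaz_mcmc")
}

#' Conjugate full-conditional draws
#'
#' The building blocks of the Gibbs sampler, exposed for testing and reuse.
#' `sample_coefficient_block()` draws a penalized coefficient vector from
#' its Gaussian full conditional
#' \deqn{N(\mu, \Sigma), \quad \Sigma^{-1} = B'B/\sigma^2 + K/\tau^2, \quad
#'   \mu = \Sigma B' r / \sigma^2}{N(mu, Sigma)}
#' given the partial residual `r`. `sample_smoothing_variance()` draws the
#' smoothing variance from `InvGamma(a + rank(K)/2, b + beta' K beta / 2)`,
#' and `sample_error_variance()` draws the error variance from
#' `InvGamma(a + n/2, b + sum(r^2)/2)`.
#'
#' @param y_partial Partial residual vector (response minus all other model
#'   components).
#' @param B Basis/design matrix of the block (n x m).
#' @param K Penalty matrix (m x m); may be rank deficient (zero matrix = no
#'   penalty).
#' @param tau2,sigma2 Current smoothing and error variances (> 0).
#' @param ridge Diagonal jitter added to the precision only if its Cholesky
#'   factorization fails (intrinsic penalties can leave the precision
#'   singular when the basis does not span the penalty null space).
#' @return `sample_coefficient_block()`: numeric vector of length `m`.
#' @export
sample_coefficient_block <- function(y_partial, B, K, tau2, sigma2,
                                     ridge = 0) {
  P <- crossprod(B) / sigma2 + K / tau2
  mu_rhs <- crossprod(B, y_partial) / sigma2
  R <- tryCatch(chol(P), error = function(e) NULL)
  if (is.null(R) && ridge > 0) {
    R <- tryCatch(chol(P + diag(ridge, ncol(P))), error = function(e) NULL)
  }
  if (is.null(R)) {
    stop_geowaz(paste0(
      "Singular full-conditional precision for a coefficient block; ",
      "consider a small `ridge` (e.g. 1e-8)."), "numerical_singularity")
  }
  mu <- backsolve(R, backsolve(R, mu_rhs, transpose = TRUE))
  drop(mu + backsolve(R, rnorm(ncol(B))))
}

#' @param beta Current coefficient vector of the block.
#' @param rank_K Rank of `K` (defaults to `qr(K)$rank`).
#' @param a,b Inverse-gamma shape and scale of the prior.
#' @return `sample_smoothing_variance()`, `sample_error_variance()`: a
#'   single positive draw.
#' @rdname sample_coefficient_block
#' @export
sample_smoothing_variance <- function(beta, K, a, b, rank_K = NULL) {
  if (a <= 0 || b <= 0) stop_geowaz("Prior `a`, `b` must be > 0.", "validation")
  rank_K <- rank_K %||% qr(K)$rank
  if (rank_K == 0) return(rinvgamma(1, a, b)) # empty penalty: prior unchanged
  quad <- drop(crossprod(beta, K %*% beta))
  if (quad < 0) {
    rlang::warn("Negative penalty quadratic form clamped to 0 (numerical).")
    quad <- 0
  }
  rinvgamma(1, a + rank_K / 2, b + quad / 2)
}

#' @param residuals Residual vector `y - eta`.
#' @rdname sample_coefficient_block
#' @export
sample_error_variance <- function(residuals, a, b) {
  if (a <= 0 || b <= 0) stop_geowaz("Prior `a`, `b` must be > 0.", "validation")
  n <- length(residuals)
  if (n < 1) stop_geowaz("Need at least one residual.", "validation")
  rinvgamma(1, a + n / 2, b + sum(residuals^2) / 2)
}

#' Fit a Bayesian geoadditive Gaussian model by Gibbs sampling
#'
#' Fits the structured additive model
#' \deqn{y_i = \omega_i'\gamma + \sum_j f_j(x_{ij}) + f_{spat}(s_i) +
#'   \varepsilon_i, \quad \varepsilon_i \sim N(0, \sigma^2)}{y = W g +
#'   sum f_j(x_j) + f_spat(s) + e}
#' where each `f_j` is a P-spline (B-spline basis with a difference penalty
#' acting as a random-walk prior), `f_spat` carries an intrinsic
#' Markov-random-field prior over regions, fixed effects have flat priors,
#' and all variance parameters have inverse-gamma hyperpriors. A
#' systematic-scan Gibbs sampler cycles the fixed effects, each penalized
#' block, each smoothing variance, and the error variance, all with
#' conjugate full conditionals.
#'
#' Identifiability: smooth and spatial terms are centered every iteration —
#' each smooth's fitted values are shifted to mean zero over the
#' observations (absorbed into the intercept, exact because the B-spline
#' rows sum to one), and the spatial effect is shifted to mean zero over
#' regions. The fitted linear predictor is invariant to this transfer.
#'
#' @param data A data frame of child-level records, or a prebuilt
#'   `geowaz_design`.
#' @param response,fixed,smooth,spatial,adjacency Passed to
#'   [build_design()] when `data` is a data frame.
#' @param priors A [prior_control()] object.
#' @param control An [mcmc_control()] object.
#' @param ridge Jitter used for rank-deficient spatial precisions when the
#'   factorization fails; a message is logged when triggered.
#' @return An object of class `geowaz_fit`; see [tidy.geowaz_fit()],
#'   [glance.geowaz_fit()], [smooth_effects()], [spatial_effect_surface()],
#'   [compute_dic()].
#' @examples
#' sim <- simulate_underweight(sim_scenario(n = 300, n_regions = 4, seed = 7))
#' fit <- fit_geoadditive(sim$data, response = "waz",
#'   fixed = "child_sex", smooth = "child_age",
#'   spatial = "region", adjacency = sim$adjacency,
#'   control = mcmc_control(400, 100, 1, seed = 7))
#' glance(fit)
#' @export
fit_geoadditive <- function(data, response = "waz", fixed = character(),
                            smooth = character(), spatial = NULL,
                            adjacency = NULL, priors = prior_control(),
                            control = mcmc_control(), ridge = 1e-8) {
  design <- if (inherits(data, "geowaz_design")) data else
    build_design(data, response = response, fixed = fixed, smooth = smooth,
                 spatial = spatial, adjacency = adjacency)
  stopifnot(inherits(priors, "geowaz_priors"), inherits(control, "geowaz_mcmc"))

  y <- design$y
  n <- length(y)
  W <- design$W
  q <- ncol(W)
  smooths <- design$smooths
  J <- length(smooths)
  has_spat <- !is.null(design$mrf)
  S <- if (has_spat) length(design$mrf$regions) else 0L

  # precomputations
  WtW <- crossprod(W)
  Rw <- chol(WtW)
  B_list <- lapply(smooths, `[[`, "B")
  BtB <- lapply(B_list, crossprod)
  K_list <- lapply(smooths, `[[`, "K")
  rank_list <- vapply(smooths, `[[`, numeric(1), "penalty_rank")
  if (has_spat) {
    ridx <- design$region_index
    counts <- tabulate(ridx, nbins = S)
    Ks <- design$mrf$K
    rank_s <- S - design$mrf$n_components
  }
  term_names <- names(smooths)
  block_prior <- function(nm) {
    o <- priors$terms[[nm]]
    c(a = o$a %||% priors$a, b = o$b %||% priors$b)
  }

  # initial state: OLS for fixed effects, zero smooths, variances 0.1
  set.seed(control$seed)
  gamma <- qr.coef(qr(W), y)
  gamma[is.na(gamma)] <- 0
  beta <- lapply(B_list, function(B) numeric(ncol(B)))
  fspat <- numeric(S)
  tau2 <- rep(0.1, J + has_spat)
  sigma2 <- 0.1

  fit_W <- drop(W %*% gamma)
  fit_sm <- lapply(B_list, function(B) numeric(n))
  fit_sp <- numeric(n)

  n_keep <- (control$iterations - control$burnin) %/% control$thin
  draws_gamma <- matrix(NA_real_, n_keep, q, dimnames = list(NULL, colnames(W)))
  draws_beta <- lapply(B_list, function(B) matrix(NA_real_, n_keep, ncol(B)))
  draws_fspat <- if (has_spat)
    matrix(NA_real_, n_keep, S, dimnames = list(NULL, design$mrf$regions))
  draws_tau2 <- matrix(NA_real_, n_keep, J + has_spat,
                       dimnames = list(NULL, c(term_names,
                                               if (has_spat) design$spatial)))
  draws_sigma2 <- numeric(n_keep)
  draws_dev <- numeric(n_keep)
  eta_sum <- numeric(n)
  kept <- 0L
  ridge_used <- FALSE

  for (it in seq_len(control$iterations)) {
    # fixed effects: flat prior => N(ls-fit of partial residual, sigma2*(W'W)^-1)
    r <- y - fit_sp
    for (j in seq_len(J)) r <- r - fit_sm[[j]]
    mu_g <- backsolve(Rw, backsolve(Rw, crossprod(W, r), transpose = TRUE))
    gamma <- drop(mu_g + sqrt(sigma2) * backsolve(Rw, rnorm(q)))
    fit_W <- drop(W %*% gamma)

    # penalized smooth blocks
    for (j in seq_len(J)) {
      r <- y - fit_W - fit_sp
      for (k in seq_len(J)) if (k != j) r <- r - fit_sm[[k]]
      P <- BtB[[j]] / sigma2 + K_list[[j]] / tau2[j]
      R <- chol(P)
      mu <- backsolve(R, backsolve(R, crossprod(B_list[[j]], r) / sigma2,
                                   transpose = TRUE))
      bj <- drop(mu + backsolve(R, rnorm(ncol(P))))
      fj <- drop(B_list[[j]] %*% bj)
      cj <- mean(fj)          # center over observations; basis rows sum to 1
      bj <- bj - cj
      fj <- fj - cj
      gamma[1] <- gamma[1] + cj
      fit_W <- fit_W + cj
      beta[[j]] <- bj
      fit_sm[[j]] <- fj
    }

    # spatial block
    if (has_spat) {
      r <- y - fit_W
      for (j in seq_len(J)) r <- r - fit_sm[[j]]
      rs <- rowsum(r, ridx)
      rhs_full <- numeric(S)
      rhs_full[as.integer(rownames(rs))] <- rs[, 1]
      P <- Ks / tau2[J + 1]
      diag(P) <- diag(P) + counts / sigma2
      R <- tryCatch(chol(P), error = function(e) NULL)
      if (is.null(R)) {
        R <- chol(P + diag(ridge, S))
        if (!ridge_used) {
          rlang::inform("Spatial precision required a ridge for factorization.")
          ridge_used <- TRUE
        }
      }
      mu <- backsolve(R, backsolve(R, rhs_full / sigma2, transpose = TRUE))
      fs <- drop(mu + backsolve(R, rnorm(S)))
      cs <- mean(fs)          # center over regions
      fs <- fs - cs
      gamma[1] <- gamma[1] + cs
      fit_W <- fit_W + cs
      fspat <- fs
      fit_sp <- fs[ridx]
    }

    # smoothing variances
    for (j in seq_len(J)) {
      pr <- block_prior(term_names[j])
      quad <- drop(crossprod(beta[[j]], K_list[[j]] %*% beta[[j]]))
      tau2[j] <- rinvgamma(1, pr["a"] + rank_list[j] / 2,
                           pr["b"] + max(quad, 0) / 2)
    }
    if (has_spat) {
      pr <- block_prior(design$spatial)
      quad <- drop(crossprod(fspat, Ks %*% fspat))
      tau2[J + 1] <- rinvgamma(1, pr["a"] + rank_s / 2,
                               pr["b"] + max(quad, 0) / 2)
    }

    # error variance
    resid <- y - fit_W - fit_sp
    for (j in seq_len(J)) resid <- resid - fit_sm[[j]]
    ssr <- sum(resid^2)
    sigma2 <- rinvgamma(1, priors$a_sigma + n / 2, priors$b_sigma + ssr / 2)
    if (!is.finite(sigma2) || sigma2 <= 0) {
      stop_geowaz(sprintf(
        "Divergent error-variance draw at iteration %d (ssr = %g).", it, ssr),
        "numerical_divergence")
    }

    if (it > control$burnin && (it - control$burnin) %% control$thin == 0) {
      kept <- kept + 1L
      draws_gamma[kept, ] <- gamma
      for (j in seq_len(J)) draws_beta[[j]][kept, ] <- beta[[j]]
      if (has_spat) draws_fspat[kept, ] <- fspat
      draws_tau2[kept, ] <- tau2
      draws_sigma2[kept] <- sigma2
      draws_dev[kept] <- n * log(2 * pi * sigma2) + ssr / sigma2
      eta_sum <- eta_sum + (y - resid)
    }
  }

  structure(
    list(design = design, priors = priors, control = control,
         gamma = draws_gamma, beta = draws_beta, fspat = draws_fspat,
         tau2 = draws_tau2, sigma2 = draws_sigma2, deviance = draws_dev,
         eta_bar = eta_sum / n_keep, n = n, n_draws = n_keep),
    class = "geowaz_fit"
  )
}

#' @export
print.geowaz_fit <- function(x, ...) {
  cat(sprintf(
    "Bayesian geoadditive Gaussian fit: n = %d, %d fixed effects, %d smooth term(s)%s\n",
    x$n, ncol(x$gamma), length(x$beta),
    if (!is.null(x$fspat)) sprintf(", spatial MRF (%d regions)", ncol(x$fspat))
    else ""))
  cat(sprintf("%d retained draws (%d iterations, %d burn-in, thin %d, seed %d)\n",
              x$n_draws, x$control$iterations, x$control$burnin,
              x$control$thin, x$control$seed))
  cat(sprintf("Posterior mean error variance sigma2 = %.4f\n", mean(x$sigma2)))
  invisible(x)
}
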