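#' Yeo-Johnson power transformation
#'
#' The Yeo-Johnson family extends the Box-Cox power transform to negative
#' values. For power `lambda` it maps
#' \deqn{\psi(x,\lambda) = ((x+1)^\lambda - 1)/\lambda}{psi = ((x+1)^l - 1)/l}
#' for `x >= 0` (with the `log(x+1)` limit at `lambda = 0`) and
#' \deqn{-((1-x)^{2-\lambda} - 1)/(2-\lambda)}{-((1-x)^(2-l) - 1)/(2-l)}
#' for `x < 0` (with the `-log(1-x)` limit at `lambda = 2`). The map is
#' continuous in both arguments, strictly increasing in `x` for every
#' `lambda`, and reduces to the identity at `lambda = 1`.
#'
#' @param x Numeric vector; negative values allowed.
#' @param lambda Single power parameter.
#' @return Transformed (or back-transformed) numeric vector.
#' @seealso [fit_yeo_johnson()] for choosing `lambda` by profile likelihood.
#' @examples
#' yeo_johnson(exp(1) - 1, lambda = 0) # log branch: exactly 1
#' yeo_johnson_inverse(yeo_johnson(-3.2, 0.5), 0.5)
#' @export
yeo_johnson <- function(x, lambda) {
  check_finite(x, "x")
  check_finite(lambda, "lambda")
  if (length(lambda) != 1L) stop_geowaz("`lambda` must be a scalar.", "validation")
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) < 1e-12) {
    out[pos] <- log1p(x[pos])
  } else {
    out[pos] <- expm1(lambda * log1p(x[pos])) / lambda
  }
  if (abs(lambda - 2) < 1e-12) {
    out[!pos] <- -log1p(-x[!pos])
  } else {
    out[!pos] <- -expm1((2 - lambda) * log1p(-x[!pos])) / (2 - lambda)
  }
  out
}

#' @rdname yeo_johnson
#' @export
yeo_johnson_inverse <- function(x, lambda) {
  check_finite(x, "x")
  check_finite(lambda, "lambda")
  out <- numeric(length(x))
  pos <- x >= 0 # transform preserves sign
  if (abs(lambda) < 1e-12) {
    out[pos] <- expm1(x[pos])
  } else {
    out[pos] <- expm1(log1p(lambda * x[pos]) / lambda)
  }
  if (abs(lambda - 2) < 1e-12) {
    out[!pos] <- -expm1(-x[!pos])
  } else {
    out[!pos] <- -expm1(log1p(-(2 - lambda) * x[!pos]) / (2 - lambda))
  }
  out
}

#' Fit the Yeo-Johnson power by Gaussian profile likelihood
#'
#' Maximizes the profile log-likelihood of a Gaussian model for the
#' transformed sample over `lambda`, using a coarse grid on `bounds`
#' followed by local refinement with [stats::optimize()]. Deterministic.
#'
#' @param x Numeric vector, `length(x) >= 10`.
#' @param bounds Search interval for `lambda` (default `c(-3, 3)`).
#' @param grid_n Number of coarse grid points.
#' @return A list of class `geowaz_yj` with elements `lambda` and
#'   `loglik` (profile log-likelihood at the optimum).
#' @export
fit_yeo_johnson <- function(x, bounds = c(-3, 3), grid_n = 61) {
  check_finite(x, "x")
  if (length(x) < 10) stop_geowaz("Need at least 10 observations.", "validation")
  ll <- function(l) yj_profile_loglik(x, l)
  grid <- seq(bounds[1], bounds[2], length.out = grid_n)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(ll, lower = lo, upper = hi, maximum = TRUE, tol = 1e-6)
  # guard: refinement can only improve on the grid optimum
  if (opt$objective < vals[i]) opt <- list(maximum = grid[i], objective = vals[i])
  structure(list(lambda = opt$maximum, loglik = opt$objective),
            class = "geowaz_yj")
}

#' @export
print.geowaz_yj <- function(x, ...) {
  cat(sprintf("Yeo-Johnson fit: lambda = %.4f (profile logLik %.2f)\n",
              x$lambda, x$loglik))
  invisible(x)
}

# Gaussian profile log-likelihood of the YJ-transformed sample; the Jacobian
# term is (lambda-1) * sum(sign(x) * log(|x|+1)).
yj_profile_loglik <- function(x, lambda) {
  z <- yeo_johnson(x, lambda)
  n <- length(x)
  s2 <- mean((z - mean(z))^2)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

#' Binned covariate-response profile
#'
#' Groups `x` into `n_bins` equal-width bins over `[min(x), max(x)]`
#' (right-closed intervals, the lowest bin closed on both sides) and reports
#' the mean response per bin — the binned screening display used to judge
#' whether a metrical covariate acts non-linearly on the outcome. Empty bins
#' are emitted with `count = 0` and `mean_y = NA`.
#'
#' @param data A data frame.
#' @param x,y Column names (strings) of the covariate and response.
#' @param n_bins Number of bins (default 30).
#' @param transform Optional: `"none"` (default), `"x"`, `"y"` or `"both"` —
#'   which variable(s) to pass through a Yeo-Johnson transform (power chosen
#'   by [fit_yeo_johnson()]) before binning.
#' @return A tibble with columns `bin`, `center`, `mean_y`, `count`.
#' @export
binned_profile <- function(data, x, y, n_bins = 30, transform = "none") {
  transform <- match.arg(transform, c("none", "x", "y", "both"))
  xv <- data[[x]]
  yv <- data[[y]]
  check_finite(xv, x)
  check_finite(yv, y)
  n_bins <- check_scalar_count(n_bins, "n_bins", min = 2L)
  if (diff(range(xv)) == 0) {
    stop_geowaz("`x` is constant; cannot bin.", "degenerate_covariate")
  }
  if (transform %in% c("x", "both")) xv <- yeo_johnson(xv, fit_yeo_johnson(xv)$lambda)
  if (transform %in% c("y", "both")) yv <- yeo_johnson(yv, fit_yeo_johnson(yv)$lambda)
  breaks <- seq(min(xv), max(xv), length.out = n_bins + 1)
  idx <- findInterval(xv, breaks, rightmost.closed = TRUE, left.open = TRUE)
  idx[xv == breaks[1]] <- 1L # lowest bin closed on the left
  counts <- tabulate(idx, nbins = n_bins)
  sums <- vapply(seq_len(n_bins), function(b) sum(yv[idx == b]), numeric(1))
  tibble::tibble(
    bin = seq_len(n_bins),
    center = (breaks[-1] + breaks[-length(breaks)]) / 2,
    mean_y = ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_),
    count = counts
  )
}

#' Histogram and kernel-density profile of a sample
#'
#' Exports plot-ready histogram densities and a Gaussian-kernel density
#' estimate (Silverman's bandwidth), plus the normal density with the
#' sample's mean and SD — the display used to judge whether a Gaussian
#' response model is adequate for the z-score distribution.
#'
#' @param x Numeric vector.
#' @param n_bins Number of histogram bins.
#' @return A list with tibbles `histogram` (`mid`, `density`, `count`) and
#'   `density` (`x`, `kde`, `normal`).
#' @export
density_profile <- function(x, n_bins = 40) {
  check_finite(x, "x")
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  d <- density(x, bw = bw.nrd0(x), kernel = "gaussian")
  list(
    histogram = tibble::tibble(mid = h$mids, density = h$density, count = h$counts),
    density = tibble::tibble(x = d$x, kde = d$y,
                             normal = dnorm(d$x, mean(x), sd(x)))
  )
}
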