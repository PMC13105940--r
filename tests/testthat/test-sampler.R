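test_that("coefficient block with no penalty and identity design is N(y, sigma2 I)", {
  set.seed(31)
  y <- rnorm(4, 2, 1)
  draws <- t(replicate(4000, sample_coefficient_block(
    y, diag(4), matrix(0, 4, 4), tau2 = 1, sigma2 = 1)))
  expect_equal(unname(colMeans(draws)), y, tolerance = 0.1)
  expect_equal(unname(apply(draws, 2, var)), rep(1, 4), tolerance = 0.15)
})

test_that("the tau2 -> Inf limit approaches the least-squares fit", {
  set.seed(33)
  n <- 60
  B <- cbind(1, rnorm(n), runif(n))
  y <- rnorm(n)
  K <- difference_penalty(3, 1)
  draws <- t(replicate(4000, sample_coefficient_block(
    y, B, K, tau2 = 1e10, sigma2 = 1)))
  ols <- qr.coef(qr(B), y)
  expect_equal(unname(colMeans(draws)), unname(ols), tolerance = 0.05)
})

test_that("singular precisions raise an informative error unless ridged", {
  B <- matrix(0, 3, 2) # no information at all, K = 0
  expect_error(sample_coefficient_block(rep(0, 3), B, matrix(0, 2, 2), 1, 1),
               class = "geowaz_error_numerical_singularity")
  expect_length(sample_coefficient_block(rep(0, 3), B, matrix(0, 2, 2), 1, 1,
                                         ridge = 1e-8), 2)
})

test_that("smoothing-variance conditional matches closed-form moments", {
  set.seed(35)
  K <- difference_penalty(6, 2)
  beta <- rnorm(6, sd = 2)
  quad <- drop(beta %*% K %*% beta)
  a <- 0.5; b <- 0.5
  n_draw <- 20000
  draws <- replicate(n_draw, sample_smoothing_variance(beta, K, a, b,
                                                       rank_K = 4))
  a_post <- a + 4 / 2; b_post <- b + quad / 2
  mc_se <- sqrt(ig_var(a_post, b_post) / n_draw)
  expect_lt(abs(mean(draws) - ig_mean(a_post, b_post)), 3 * mc_se)

  # beta in the null space: quadratic form zero, IG(a + rank/2, b)
  aff <- 1 + 2 * seq_len(6)
  draws0 <- replicate(5000, sample_smoothing_variance(aff, K, 2, 3,
                                                      rank_K = 4))
  expect_equal(mean(draws0), ig_mean(2 + 2, 3), tolerance = 0.05)

  # empty penalty: prior returned unchanged
  draws_p <- replicate(5000, sample_smoothing_variance(beta, matrix(0, 6, 6),
                                                       3, 4, rank_K = 0))
  expect_equal(mean(draws_p), ig_mean(3, 4), tolerance = 0.1)
})

test_that("error-variance conditional concentrates on the truth", {
  set.seed(37)
  # all-zero residuals: IG(a + n/2, b)
  d0 <- replicate(4000, sample_error_variance(numeric(50), 2, 3))
  expect_equal(mean(d0), ig_mean(2 + 25, 3), tolerance = 0.02)

  r <- rnorm(1000, 0, sqrt(1.35)) # scale echoing a typical WAZ error variance
  draws <- replicate(4000, sample_error_variance(r, 0.001, 0.001))
  a_post <- 0.001 + 500; b_post <- 0.001 + sum(r^2) / 2
  expect_lt(abs(mean(draws) - 1.35), 3 * sqrt(ig_var(a_post, b_post)))
})

test_that("identical seeds give bit-identical retained draws", {
  sim <- tiny_sim()
  ctl <- mcmc_control(120, 40, 2, seed = 123)
  f1 <- fit_geoadditive(sim$data, smooth = "child_age", spatial = "region",
                        adjacency = sim$adjacency, control = ctl)
  f2 <- fit_geoadditive(sim$data, smooth = "child_age", spatial = "region",
                        adjacency = sim$adjacency, control = ctl)
  expect_identical(f1$gamma, f2$gamma)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$sigma2, f2$sigma2)
  expect_equal(f1$n_draws, (120 - 40) %/% 2)
})

test_that("smooth and spatial blocks are centred every retained draw", {
  fit <- fit_tiny()
  for (nm in names(fit$beta)) {
    fitted_draws <- fit$beta[[nm]] %*% t(fit$design$smooths[[nm]]$B)
    expect_lt(max(abs(rowMeans(fitted_draws))), 1e-10)
  }
  expect_lt(max(abs(rowMeans(fit$fspat))), 1e-10)
})

test_that("stored draws reproduce the running posterior-mean predictor", {
  fit <- fit_tiny()
  d <- fit$design
  eta <- fit$gamma %*% t(d$W)
  for (nm in names(fit$beta)) eta <- eta + fit$beta[[nm]] %*% t(d$smooths[[nm]]$B)
  eta <- eta + fit$fspat[, d$region_index]
  expect_equal(unname(colMeans(eta)), unname(fit$eta_bar), tolerance = 1e-8)
})

test_that("posterior summaries are invariant to the smooth update order", {
  sim <- tiny_sim()
  ctl <- mcmc_control(800, 300, 1, seed = 77)
  f_ab <- fit_geoadditive(sim$data, smooth = c("child_age", "mother_bmi"),
                          control = ctl)
  f_ba <- fit_geoadditive(sim$data, smooth = c("mother_bmi", "child_age"),
                          control = ctl)
  g1 <- glance(f_ab); g2 <- glance(f_ba)
  expect_equal(g1$sigma2, g2$sigma2, tolerance = 0.05)
  e1 <- smooth_effects(f_ab, "child_age", n_grid = 12)
  e2 <- smooth_effects(f_ba, "child_age", n_grid = 12)
  # pointwise posterior means agree within MC error (a few posterior SEs)
  expect_lt(max(abs(e1$mean - e2$mean)), 0.2)
})

test_that("invalid MCMC configurations are rejected", {
  expect_error(mcmc_control(100, 100, 1), class = "geowaz_error_validation")
  expect_error(mcmc_control(100, 10, 0), class = "geowaz_error_validation")
  expect_error(prior_control(a = 0), class = "geowaz_error_validation")
})
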