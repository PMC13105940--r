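test_that("B-spline rows are a partition of unity and match de Boor recursion", {
  set.seed(21)
  x <- c(runif(40, 0, 59), 0, 59) # include both boundaries
  sb <- bspline_basis(x, degree = 3, n_knots = 8)
  expect_equal(unname(rowSums(sb$B)), rep(1, length(x)), tolerance = 1e-10)
  expect_true(all(sb$B >= 0))
  expect_equal(ncol(sb$B), 8 + 3 + 1)
  # independent recursive evaluation at interior points
  for (i in sample(which(x > 0 & x < 59), 10)) {
    expect_equal(unname(sb$B[i, ]), deboor_row(sb$knots, 3, x[i]),
                 tolerance = 1e-10)
  }
})

test_that("linear B-spline puts weight (0.5, 0.5) midway between knots", {
  sb <- bspline_basis(c(0, 0.5, 1, 2), degree = 1, n_knots = 1)
  # inner knots {0, 1, 2}: hat functions centred there
  expect_equal(unname(sb$B[2, ]), c(0.5, 0.5, 0))
  expect_equal(unname(sb$B[1, ]), c(1, 0, 0))
  expect_error(bspline_basis(rep(2, 10)),
               class = "geowaz_error_degenerate_covariate")
})

test_that("difference penalties have the right form, rank and null space", {
  expect_equal(difference_penalty(3, 1),
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3))
  K <- difference_penalty(5, 2)
  expect_equal(qr(K)$rank, 3) # m - d
  expect_equal(K, t(K))
  expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  # RW2 annihilates affine coefficient vectors, and only those
  for (m in c(4, 9, 24)) {
    K2 <- difference_penalty(m, 2)
    aff <- 2.5 - 0.7 * seq_len(m)
    expect_equal(drop(aff %*% K2 %*% aff), 0, tolerance = 1e-10)
    quad <- seq_len(m)^2
    expect_gt(drop(quad %*% K2 %*% quad), 1e-6)
  }
  expect_error(difference_penalty(3, 3), class = "geowaz_error_invalid_order")
})

test_that("MRF precision encodes neighbour counts and pairwise differences", {
  pair <- mrf_precision(tibble::tibble(from = "A", to = "B"))
  expect_equal(unname(pair$K), matrix(c(1, -1, -1, 1), 2, 2))

  path <- mrf_precision(tibble::tibble(from = c("1", "2"), to = c("2", "3")))
  expect_equal(unname(diag(path$K)), c(1, 2, 1))
  expect_equal(path$K["1", "2"], -1)
  expect_equal(path$K["1", "3"], 0)

  set.seed(23)
  lat <- region_lattice(7)
  mrf <- mrf_precision(lat$edges, regions = lat$regions)
  expect_equal(unname(rowSums(mrf$K)), rep(0, 7), tolerance = 1e-12)
  expect_equal(qr(mrf$K)$rank, 7 - mrf$n_components)
  for (rep in 1:5) {
    beta <- rnorm(7)
    expect_equal(drop(beta %*% mrf$K %*% beta),
                 mrf_quadform_direct(mrf$edges, mrf$regions, beta),
                 tolerance = 1e-10)
  }
  expect_equal(drop(rep(2, 7) %*% mrf$K %*% rep(2, 7)), 0, tolerance = 1e-12)
})

test_that("islands are linked with a warning, bad edges rejected", {
  expect_warning(
    mrf <- mrf_precision(tibble::tibble(from = "A", to = "B"),
                         regions = c("A", "B", "C")),
    class = "geowaz_warning_island")
  expect_equal(mrf$n_components, 1)
  expect_equal(sum(diag(mrf$K)), 4) # two edges now

  kept <- suppressWarnings(
    mrf_precision(tibble::tibble(from = "A", to = "B"),
                  regions = c("A", "B", "C"), island_action = "keep"))
  expect_equal(kept$n_components, 2)
  expect_equal(qr(kept$K)$rank, 3 - 2)

  expect_error(mrf_precision(tibble::tibble(from = "A", to = "Z"),
                             regions = c("A", "B")),
               class = "geowaz_error_validation")
  # self-loops are dropped
  self <- mrf_precision(tibble::tibble(from = c("A", "A"), to = c("A", "B")))
  expect_equal(unname(diag(self$K)), c(1, 1))
})

test_that("design assembly produces conformable blocks and the paper layout", {
  sim <- tiny_sim()
  # intercept-only
  d0 <- build_design(sim$data, "waz")
  expect_equal(unname(d0$W), matrix(1, nrow(sim$data), 1))

  d <- build_design(sim$data, "waz",
                    fixed = c("child_sex", "residence", "electricity",
                              "head_sex", "diarrhoea", "anaemia", "mother_edu"),
                    smooth = c("child_age", "mother_age", "mother_bmi"),
                    spatial = "region", adjacency = sim$adjacency)
  expect_equal(ncol(d$W), 12) # intercept + 1+1+1+1+1+3+3 dummies
  expect_equal(sum(grepl("^sx\\(", d$term_labels)), 4) # 3 smooths + spatial
  # eta reconstruction is conformable for arbitrary coefficients
  set.seed(29)
  gamma <- rnorm(ncol(d$W))
  eta <- drop(d$W %*% gamma)
  for (sm in d$smooths) eta <- eta + drop(sm$B %*% rnorm(ncol(sm$B)))
  eta <- eta + rnorm(length(d$mrf$regions))[d$region_index]
  expect_equal(length(eta), length(d$y))

  # collinearity is reported with the offending column
  bad <- dplyr::mutate(sim$data, dup = child_sex)
  expect_error(build_design(bad, "waz", fixed = c("child_sex", "dup")),
               class = "geowaz_error_collinearity")
})

test_that("complete-case filtering drops and counts missing rows", {
  sim <- tiny_sim()
  dat <- sim$data
  dat$waz[c(3, 10)] <- NA
  dat$mother_bmi[5] <- NA
  expect_message(
    d <- build_design(dat, "waz", smooth = "mother_bmi"),
    "dropped 3")
  expect_equal(d$n_dropped, 3)
  expect_equal(length(d$y), nrow(dat) - 3)
})

test_that("adjacency files round-trip", {
  edges <- tibble::tibble(from = c("A", "B"), to = c("B", "C"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_adjacency(edges, path)
  expect_equal(read_adjacency(path), edges)
})
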