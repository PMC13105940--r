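test_that("truth functions have the documented shapes and centring", {
  tf <- default_truth_functions()
  # maternal BMI: inverted U, maximal strictly inside the healthy range
  bmi_grid <- seq(12, 50, by = 0.1)
  peak <- bmi_grid[which.max(tf$mother_bmi(bmi_grid))]
  expect_gt(peak, 18.5)
  expect_lt(peak, 30)
  expect_gt(tf$mother_bmi(peak), tf$mother_bmi(13))
  expect_gt(tf$mother_bmi(peak), tf$mother_bmi(45))

  # maternal age: flat over 15-35, declining after
  expect_lt(abs(tf$mother_age(20) - tf$mother_age(30)), 0.1)
  expect_lt(tf$mother_age(45), tf$mother_age(30))

  # child age: worsening to ~10 months, then plateauing by ~30
  expect_gt(tf$child_age(0), tf$child_age(10))
  expect_lt(abs(tf$child_age(35) - tf$child_age(59)),
            abs(tf$child_age(0) - tf$child_age(10)) / 4)

  # centred under the generating covariate distributions
  p <- stats::ppoints(20001)
  expect_equal(mean(tf$child_age(stats::quantile(0:59, p, names = FALSE))), 0,
               tolerance = 1e-3)
  expect_equal(mean(tf$mother_bmi(geowaz:::qtruncnorm(p, 21, 3.5, 12, 50))), 0,
               tolerance = 1e-3)
})

test_that("degenerate scenario with no effects and no noise gives y == 0", {
  tf0 <- default_truth_functions(amplitude = 0)
  gamma0 <- setNames(rep(0, 12), names(sim_scenario(n = 10)$gamma))
  sc <- sim_scenario(n = 50, n_regions = 4, clusters_per_region = 2,
                     gamma = gamma0, truth = tf0, tau_spat = 0, sigma = 0,
                     seed = 5)
  sim <- simulate_underweight(sc)
  expect_equal(sim$data$waz, rep(0, 50))
})

test_that("response variance decomposes into signal plus noise", {
  sc <- sim_scenario(n = 10000, n_regions = 6, clusters_per_region = 5,
                     seed = 61)
  sim <- simulate_underweight(sc)
  v_pred <- var(sim$truth$linear_predictor)
  expect_equal(var(sim$data$waz), v_pred + sc$sigma^2,
               tolerance = 0.05 * (v_pred + sc$sigma^2))
})

test_that("default categorical frequencies match the survey shares", {
  sim <- simulate_underweight(sim_scenario(seed = 63)) # default n = 10641
  n <- nrow(sim$data)
  expect_equal(n, 10641)
  rural <- mean(sim$data$residence == "rural")
  se <- sqrt(0.8145 * (1 - 0.8145) / n)
  expect_lt(abs(rural - 0.8145), 4 * se)
  noedu <- mean(sim$data$mother_edu == "no_education")
  expect_equal(noedu, 6838 / 10641, tolerance = 0.02)
  expect_true(all(sim$data$child_age >= 0 & sim$data$child_age <= 59))
  expect_true(all(sim$data$mother_age >= 15 & sim$data$mother_age <= 49))
  expect_true(all(sim$data$mother_bmi >= 12 & sim$data$mother_bmi <= 50))
})

test_that("true spatial effects sum to zero per connected component", {
  sim <- tiny_sim()
  expect_equal(sum(sim$truth$spatial$effect), 0, tolerance = 1e-10)

  # disconnected graph: centred per component, with a warning
  edges <- tibble::tibble(from = c("A", "C"), to = c("B", "D"))
  sc <- sim_scenario(n = 40, adjacency = edges, clusters_per_region = 2,
                     seed = 9)
  expect_warning(sim2 <- simulate_underweight(sc), "components")
  eff <- sim2$truth$spatial
  expect_equal(sum(eff$effect[eff$region %in% c("A", "B")]), 0,
               tolerance = 1e-10)
  expect_equal(sum(eff$effect[eff$region %in% c("C", "D")]), 0,
               tolerance = 1e-10)
})

test_that("generator output passes design validation with zero dropped rows", {
  sim <- tiny_sim()
  d <- build_design(sim$data, "waz",
                    fixed = c("child_sex", "residence", "electricity",
                              "head_sex", "diarrhoea", "anaemia", "mother_edu"),
                    smooth = c("child_age", "mother_age", "mother_bmi"),
                    spatial = "region", adjacency = sim$adjacency)
  expect_equal(d$n_dropped, 0)
  expect_equal(length(d$y), nrow(sim$data))
})

test_that("fixtures are written completely and byte-identically per seed", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- make_fixture("tiny", dir1, seed = 99)
  p2 <- make_fixture("tiny", dir2, seed = 99)
  expect_true(all(file.exists(p1)))
  dat <- readr::read_csv(p1["data"], show_col_types = FALSE)
  expect_equal(nrow(dat), 200)
  for (f in names(p1)) {
    expect_identical(readBin(p1[[f]], "raw", file.size(p1[[f]])),
                     readBin(p2[[f]], "raw", file.size(p2[[f]])),
                     label = f)
  }
  truth <- jsonlite::read_json(p1["truth"], simplifyVector = TRUE)
  expect_equal(sum(truth$spatial$effect), 0, tolerance = 1e-8)
})
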