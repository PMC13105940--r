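test_that("IDW reproduces sources exactly and averages equidistant pairs", {
  src <- tibble::tibble(lon = c(38, 40), lat = c(8, 8), value = c(1, 5))
  # grid point on a source: zero-distance rule
  at_src <- idw_interpolate(src, grid = tibble::tibble(lon = 38, lat = 8))
  expect_equal(at_src$value, 1)
  # midpoint on the same parallel is equidistant: arithmetic mean
  mid <- idw_interpolate(src, grid = tibble::tibble(lon = 39, lat = 8))
  expect_equal(mid$value, 3, tolerance = 1e-10)
})

test_that("IDW matches the direct weighted-sum formula on random instances", {
  set.seed(47)
  for (p in c(1, 2, 3.5)) {
    src <- tibble::tibble(lon = runif(5, 33, 48), lat = runif(5, 3, 15),
                          value = rnorm(5))
    g <- tibble::tibble(lon = runif(3, 33, 48), lat = runif(3, 3, 15))
    got <- idw_interpolate(src, grid = g, power = p)
    for (i in 1:3) {
      d <- geosphere::distHaversine(c(g$lon[i], g$lat[i]),
                                    cbind(src$lon, src$lat)) / 1000
      expect_equal(got$value[i],
                   sum(d^(-p) * src$value) / sum(d^(-p)), tolerance = 1e-10)
    }
    # bounds containment and shift equivariance
    expect_true(all(got$value >= min(src$value) & got$value <= max(src$value)))
    shifted <- idw_interpolate(dplyr::mutate(src, value = value + 10),
                               grid = g, power = p)
    expect_equal(shifted$value, got$value + 10, tolerance = 1e-10)
  }
})

test_that("duplicate conflicting sources are averaged with a warning", {
  src <- tibble::tibble(lon = c(38, 38, 40), lat = c(8, 8, 9),
                        value = c(1, 3, 7))
  expect_warning(
    got <- idw_interpolate(src, grid = tibble::tibble(lon = 38, lat = 8)),
    "conflicting")
  expect_equal(got$value, 2)
})

test_that("hotspot rule flags strict exceedance of the grid quantile", {
  const <- tibble::tibble(lon = 1:5, lat = 1, value = 2)
  expect_equal(sum(hotspot_classify(const)$hotspot), 0) # no strict exceedance

  g <- tibble::tibble(lon = 1:100, lat = 1, value = c(rep(0, 99), 10))
  hs <- hotspot_classify(g, prob = 0.99)
  expect_equal(which(hs$hotspot), 100)

  set.seed(49)
  g2 <- tibble::tibble(lon = 1:200, lat = 1, value = rnorm(200))
  hs2 <- hotspot_classify(g2, prob = 0.8)
  expect_equal(sum(hs2$hotspot), 40) # top quintile of 200 cells
})

test_that("spatial surface flags match quantiles and widening moves to null", {
  fit <- fit_tiny()
  surf <- spatial_effect_surface(fit)
  expect_equal(surf$significance,
               dplyr::case_when(surf$q2.5 > 0 ~ "positive",
                                surf$q97.5 < 0 ~ "negative",
                                TRUE ~ "null"))
  expect_lt(abs(mean(surf$mean)), 1e-8) # centred across regions

  # all-zero spatial draws: every region null with mean zero
  zero_fit <- fit
  zero_fit$fspat <- matrix(0, fit$n_draws, ncol(fit$fspat),
                           dimnames = dimnames(fit$fspat))
  zsurf <- spatial_effect_surface(zero_fit)
  expect_true(all(zsurf$significance == "null"))
  expect_true(all(zsurf$mean == 0))

  # 99% intervals can only move classes toward null
  wide <- posterior_summary(fit$fspat, probs = c(0.005, 0.5, 0.995))
  cls99 <- dplyr::case_when(wide$q0.5 > 0 ~ "positive",
                            wide$q99.5 < 0 ~ "negative", TRUE ~ "null")
  moved <- surf$significance != cls99
  expect_true(all(cls99[moved] == "null"))
})

test_that("residual spatial pattern recovers an injected regional shift", {
  sim <- tiny_sim()
  dat <- sim$data
  shift_region <- "R02"
  dat$waz <- dat$waz + 0.5 * (dat$region == shift_region)
  fit <- fit_geoadditive(dat, smooth = c("child_age", "mother_bmi"),
                         fixed = "child_sex",
                         control = mcmc_control(400, 150, 1, seed = 21))
  pat <- residual_spatial_pattern(fit, region_col = "region")
  others <- pat$mean_residual[pat$region != shift_region]
  expect_lt(abs(pat$mean_residual[pat$region == shift_region] - mean(others) -
                  0.5), 0.25)
  expect_true(all(pat$count > 0))
})

test_that("region-mean residuals shrink with sample size on correct models", {
  fits <- lapply(c(400, 1600), function(n) {
    sim <- simulate_underweight(sim_scenario(
      n = n, n_regions = 4, clusters_per_region = 3, tau_spat = 0, seed = 31))
    fit_geoadditive(sim$data, smooth = "child_age",
                    control = mcmc_control(300, 100, 1, seed = 5))
  })
  m <- vapply(fits, function(f) {
    max(abs(residual_spatial_pattern(f, region_col = "region")$mean_residual))
  }, numeric(1))
  # quadrupling n should roughly halve the worst region mean; allow slack
  expect_lt(m[2], m[1] * 1.1)
})

test_that("severity sources flip sign and aggregate per cluster or region", {
  fit <- fit_tiny()
  src_cl <- predict_severity_sources(fit, by = "cluster")
  expect_true(all(c("lon", "lat", "value") %in% names(src_cl)))
  expect_equal(mean(src_cl$value > 0), mean(fit$eta_bar < 0), tolerance = 0.3)
  src_rg <- predict_severity_sources(fit, by = "region")
  expect_equal(nrow(src_rg), length(fit$design$mrf$regions))
})
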