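# Independent oracles used across tests. These deliberately re-derive
# quantities by a different route than the package implementation.

# Recursive Cox-de Boor evaluation of a single B-spline basis function
# B_{i,deg}(x) on knot vector `knots` (0-based index i).
deboor_basis <- function(i, deg, knots, x) {
  if (deg == 0) {
    return(as.numeric(knots[i + 1] <= x & x < knots[i + 2]))
  }
  d1 <- knots[i + deg + 1] - knots[i + 1]
  d2 <- knots[i + deg + 2] - knots[i + 2]
  a <- if (d1 > 0) (x - knots[i + 1]) / d1 * deboor_basis(i, deg - 1, knots, x) else 0
  b <- if (d2 > 0) (knots[i + deg + 2] - x) / d2 *
    deboor_basis(i + 1, deg - 1, knots, x) else 0
  a + b
}

# Full basis row by recursion (columns as in splineDesign's ordering).
deboor_row <- function(knots, degree, x) {
  m <- length(knots) - degree - 1
  vapply(seq_len(m) - 1, deboor_basis, numeric(1), deg = degree,
         knots = knots, x = x)
}

# Explicit sum of squared neighbour differences for an MRF quadratic form.
mrf_quadform_direct <- function(edges, regions, beta) {
  i <- match(edges$from, regions)
  j <- match(edges$to, regions)
  sum((beta[i] - beta[j])^2)
}

# Inverse-gamma moments (shape a, scale b).
ig_mean <- function(a, b) b / (a - 1)
ig_var <- function(a, b) b^2 / ((a - 1)^2 * (a - 2))

# Small ready-made simulated dataset + adjacency shared by several tests.
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_underweight(
        sim_scenario(n = 400, n_regions = 4, clusters_per_region = 3,
                     seed = 42))
    }
    cache
  }
})

fit_tiny <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- tiny_sim()
      cache <<- fit_geoadditive(
        sim$data, response = "waz", fixed = c("child_sex", "residence"),
        smooth = c("child_age", "mother_bmi"),
        spatial = "region", adjacency = sim$adjacency,
        control = mcmc_control(500, 200, 1, seed = 9))
    }
    cache
  }
})
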