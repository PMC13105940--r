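#' Rook-adjacency lattice over regions
#'
#' Arranges `n_regions` labelled regions on a near-square grid and connects
#' horizontal/vertical neighbours — the default study-area graph for
#' simulations when no real adjacency is supplied.
#'
#' @param n_regions Number of regions (>= 2).
#' @return A list: `regions` (labels `R01`, ...), `edges` (tibble `from`,
#'   `to`), `layout` (tibble `region`, `row`, `col`).
#' @export
region_lattice <- function(n_regions) {
  n_regions <- check_scalar_count(n_regions, "n_regions", min = 2L)
  nc <- ceiling(sqrt(n_regions))
  regions <- sprintf("R%02d", seq_len(n_regions))
  row <- (seq_len(n_regions) - 1) %/% nc + 1
  col <- (seq_len(n_regions) - 1) %% nc + 1
  edges <- list()
  for (i in seq_len(n_regions)) {
    right <- which(row == row[i] & col == col[i] + 1)
    down <- which(row == row[i] + 1 & col == col[i])
    for (j in c(right, down)) {
      edges[[length(edges) + 1]] <- c(regions[i], regions[j])
    }
  }
  edges <- tibble::as_tibble(do.call(rbind, edges), .name_repair = ~ c("from", "to"))
  list(regions = regions, edges = edges,
       layout = tibble::tibble(region = regions, row = row, col = col))
}

#' Ground-truth smooth functions for simulation
#'
#' Closed-form curves qualitatively matching the non-linear covariate
#' effects reported for childhood underweight: the child-age effect
#' declines steeply over the first ~10 months and plateaus by ~30 months;
#' the maternal-BMI effect is an inverted U peaking in the healthy BMI
#' range (maximal inside 18.5-30, lower at both extremes); the maternal-age
#' effect is flat from 15 to ~35 years and declines after 35. Each curve is
#' centred (mean zero) and scaled to a target SD under its generating
#' covariate distribution, so the response-scale effect size is explicit.
#'
#' @param amplitude Per-curve SD on the response scale (default 0.35, about
#'   0.3 of the default error SD — large enough that recovery is testable
#'   at moderate n).
#' @return A named list of functions `child_age`, `mother_age`,
#'   `mother_bmi`, each vectorized over its covariate's units.
#' @export
default_truth_functions <- function(amplitude = 0.35) {
  shapes <- list(
    child_age = function(t) -(1 - exp(-t / 8)),
    mother_age = function(a) -log1p(exp((a - 35) / 2.5)),
    mother_bmi = function(b) exp(-(b - 23)^2 / (2 * 5^2))
  )
  # deterministic quadrature sample through each covariate's quantile map
  p <- stats::ppoints(4001)
  ref <- list(
    child_age = quantile(0:59, probs = p, type = 7, names = FALSE),
    mother_age = qtruncnorm(p, 28, 7, 15, 49),
    mother_bmi = qtruncnorm(p, 21, 3.5, 12, 50)
  )
  purrr::imap(shapes, function(f, nm) {
    v <- f(ref[[nm]])
    mu <- mean(v)
    s <- sd(v)
    force(f); force(mu); force(s)
    function(x) (f(x) - mu) / s * amplitude
  })
}

# quantile function of a truncated normal
qtruncnorm <- function(p, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  qnorm(plo + p * (phi - plo), mean, sd)
}

#' Simulation scenario for DHS-like child anthropometry data
#'
#' Bundles every knob of the synthetic-data generator: sample size, region
#' graph, clusters, true fixed effects, true smooth curves, spatial and
#' error scales, covariate distributions, and seed. Defaults emulate the
#' structure of the 2016 Ethiopian DHS underweight sample: n = 10,641
#' children in 11 regions and ~645 clusters; 81.45% rural residence;
#' maternal education shares 64.27/25.17/6.90/3.67%; diarrhoea-positive
#' share 82.94%; child age uniform over 0-59 months; maternal age
#' truncated-normal on 15-49 years; maternal BMI truncated-normal on
#' 12-50 kg/m2; true fixed-effect sizes follow the reported posterior
#' means (e.g. +0.0837 WAZ for female children, -0.1976 for no
#' electricity); error SD 1.162 (variance 1.351).
#'
#' @param n Number of children.
#' @param n_regions Number of regions (used when `adjacency` is `NULL`; a
#'   rook lattice is generated).
#' @param adjacency Optional edge list tibble (`from`, `to`) naming the
#'   region graph.
#' @param clusters_per_region Sampling clusters per region.
#' @param gamma Named vector of true fixed effects in model.matrix coding
#'   (must include `(Intercept)`).
#' @param truth List of true smooth functions as from
#'   [default_truth_functions()].
#' @param tau_spat Spatial smoothing SD for the intrinsic-MRF draw of the
#'   true region effects (0 disables spatial signal).
#' @param sigma True error SD.
#' @param cat_probs Named list of per-factor level probabilities (first
#'   level = reference).
#' @param bbox Lon/lat bounding box `c(lon_min, lat_min, lon_max, lat_max)`
#'   tiled by the regions (default an Ethiopia-like extent).
#' @param seed Integer seed.
#' @return A list of class `geowaz_scenario`.
#' @export
sim_scenario <- function(n = 10641, n_regions = 11, adjacency = NULL,
                         clusters_per_region = 59,
                         gamma = NULL, truth = default_truth_functions(),
                         tau_spat = 0.55, sigma = sqrt(1.3511),
                         cat_probs = NULL,
                         bbox = c(33, 3, 48, 15), seed = 1L) {
  n <- check_scalar_count(n, "n")
  if (is.null(adjacency)) {
    lat <- region_lattice(n_regions)
    adjacency <- lat$edges
    regions <- lat$regions
    layout <- lat$layout
  } else {
    adjacency <- tibble::as_tibble(as.data.frame(adjacency)[1:2],
                                   .name_repair = ~ c("from", "to"))
    regions <- sort(unique(c(adjacency$from, adjacency$to)))
    nc <- ceiling(sqrt(length(regions)))
    layout <- tibble::tibble(region = regions,
                             row = (seq_along(regions) - 1) %/% nc + 1,
                             col = (seq_along(regions) - 1) %% nc + 1)
  }
  if (length(regions) < 2) stop_geowaz("Need at least 2 regions.", "validation")

  gamma <- gamma %||% c(
    "(Intercept)" = -1.1037,
    child_sexfemale = 0.0837,
    residencerural = -0.0296,
    electricityno = -0.1976,
    head_sexfemale = -0.0521,
    diarrhoeayes = 0.2161,
    anaemiasevere = -0.5319,
    anaemiamoderate = 0.2998,
    anaemiamild = 0.0139,
    mother_eduprimary = -0.0946,
    mother_edusecondary = 0.1232,
    mother_eduhigher = 0.2277
  )
  cat_probs <- cat_probs %||% list(
    child_sex = c(male = 0.5, female = 0.5),
    residence = c(urban = 0.1855, rural = 0.8145),
    electricity = c(yes = 0.30, no = 0.70),
    head_sex = c(male = 0.75, female = 0.25),
    diarrhoea = c(no = 1815 / 10641, yes = 8826 / 10641),
    anaemia = c(not_anaemic = 0.43, severe = 0.05, moderate = 0.28,
                mild = 0.24),
    mother_edu = c(no_education = 6838 / 10641, primary = 2678 / 10641,
                   secondary = 734 / 10641, higher = 391 / 10641)
  )
  for (nm in names(cat_probs)) {
    p <- cat_probs[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop_geowaz(sprintf("Probabilities for `%s` must be in [0,1] and sum to 1.",
                          nm), "validation")
    }
  }
  if (!is.finite(sigma) || sigma < 0) {
    stop_geowaz("`sigma` must be non-negative.", "validation")
  }
  structure(
    list(n = n, regions = regions, adjacency = adjacency, layout = layout,
         clusters_per_region = check_scalar_count(clusters_per_region,
                                                  "clusters_per_region"),
         gamma = gamma, truth = truth, tau_spat = tau_spat, sigma = sigma,
         cat_probs = cat_probs, bbox = bbox, seed = as.integer(seed)),
    class = "geowaz_scenario"
  )
}

#' Simulate a DHS-like child anthropometry dataset with known truth
#'
#' Draws a clustered child-level dataset from a
#' geoadditive Gaussian model: true region effects come from the intrinsic
#' MRF prior on the scenario graph (spectral draw, null space set to zero,
#' so effects sum to zero exactly per connected component), cluster
#' coordinates are placed inside per-region tiles of the bounding box, and
#' the response is the linear predictor plus Gaussian noise, exactly by
#' construction. Fully reproducible from the scenario seed.
#'
#' @param scenario A [sim_scenario()] object.
#' @return A list of class `geowaz_sim`: `data` (tibble, one row per
#'   child), `truth` (list: `spatial` tibble, `smooth` grid tibble,
#'   `gamma`, `linear_predictor`, `sigma`), `adjacency` (edge tibble),
#'   `scenario`.
#' @export
simulate_underweight <- function(scenario) {
  stopifnot(inherits(scenario, "geowaz_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n
  regions <- scenario$regions
  S <- length(regions)

  # true spatial effects from the intrinsic MRF prior (spectral form)
  mrf <- mrf_precision(scenario$adjacency, regions = regions,
                       island_action = "keep")
  if (mrf$n_components > 1) {
    rlang::warn(sprintf(
      "Scenario graph has %d components; spatial effects centred per component.",
      mrf$n_components))
  }
  eg <- eigen(mrf$K, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  fspat <- if (scenario$tau_spat > 0 && any(pos)) {
    drop(eg$vectors[, pos, drop = FALSE] %*%
           (rnorm(sum(pos)) / sqrt(eg$values[pos]))) * scenario$tau_spat
  } else {
    numeric(S)
  }
  names(fspat) <- regions

  # clusters: uniform inside each region's tile of the bounding box
  layout <- scenario$layout
  nr <- max(layout$row); nc <- max(layout$col)
  bbox <- scenario$bbox
  tile_w <- (bbox[3] - bbox[1]) / nc
  tile_h <- (bbox[4] - bbox[2]) / nr
  cl <- purrr::map_dfr(seq_len(S), function(i) {
    k <- scenario$clusters_per_region
    tibble::tibble(
      region = regions[i],
      cluster = paste0(regions[i], "_C", seq_len(k)),
      lon = bbox[1] + (layout$col[i] - 1 + runif(k)) * tile_w,
      lat = bbox[2] + (nr - layout$row[i] + runif(k)) * tile_h)
  })

  region_i <- sample.int(S, n, replace = TRUE)
  cluster_i <- sample.int(scenario$clusters_per_region, n, replace = TRUE)
  cl_row <- match(paste0(regions[region_i], "_C", cluster_i), cl$cluster)

  draw_factor <- function(p) {
    factor(sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
  }
  dat <- tibble::tibble(
    child_age = sample(0:59, n, replace = TRUE),
    mother_age = qtruncnorm(runif(n), 28, 7, 15, 49),
    mother_bmi = qtruncnorm(runif(n), 21, 3.5, 12, 50)
  )
  for (nm in names(scenario$cat_probs)) {
    dat[[nm]] <- draw_factor(scenario$cat_probs[[nm]])
  }
  dat$region <- regions[region_i]
  dat$cluster <- cl$cluster[cl_row]
  dat$lon <- cl$lon[cl_row]
  dat$lat <- cl$lat[cl_row]

  fml <- stats::reformulate(names(scenario$cat_probs))
  W <- model.matrix(fml, data = dat)
  gamma <- scenario$gamma
  missing <- setdiff(colnames(W), names(gamma))
  if (length(missing) > 0) {
    stop_geowaz(paste0("Scenario `gamma` lacks coefficients: ",
                       paste(missing, collapse = ", ")), "validation")
  }
  eta <- drop(W %*% gamma[colnames(W)])
  smooth_terms <- intersect(names(scenario$truth), names(dat))
  for (nm in smooth_terms) eta <- eta + scenario$truth[[nm]](dat[[nm]])
  eta <- unname(eta + fspat[region_i])
  dat$waz <- eta + rnorm(n, 0, scenario$sigma)
  dat$underweight <- classify_underweight(dat$waz)

  smooth_grid <- purrr::map_dfr(smooth_terms, function(nm) {
    x <- seq(min(dat[[nm]]), max(dat[[nm]]), length.out = 101)
    tibble::tibble(term = nm, x = x, value = scenario$truth[[nm]](x))
  })
  structure(
    list(data = dat,
         truth = list(spatial = tibble::tibble(region = regions,
                                               effect = unname(fspat)),
                      smooth = smooth_grid, gamma = gamma,
                      linear_predictor = eta, sigma = scenario$sigma),
         adjacency = mrf$edges, scenario = scenario),
    class = "geowaz_sim"
  )
}

#' Write a synthetic fixture to disk
#'
#' Generates a scenario of the requested size and writes plain-text files:
#' `data.csv` (child records), `adjacency.txt` (edge list), `truth.json`
#' (spatial effects, smooth grids, true coefficients and error SD), and
#' `scenario.json` (the scalar scenario settings). Regeneration with the
#' same seed is byte-identical.
#'
#' @param size `"tiny"` (200 children, 4 regions — fits in seconds),
#'   `"small"` (2,000 children, 11 regions), or `"paper_scale"` (10,641
#'   children, 11 regions, ~645 clusters).
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a named character vector of the written paths.
#' @export
make_fixture <- function(size = c("tiny", "small", "paper_scale"),
                         dir = tempfile("geowaz_fixture_"), seed = 2026L) {
  size <- match.arg(size)
  cfg <- switch(size,
    tiny = list(n = 200, n_regions = 4, clusters = 3),
    small = list(n = 2000, n_regions = 11, clusters = 10),
    paper_scale = list(n = 10641, n_regions = 11, clusters = 59))
  scenario <- sim_scenario(n = cfg$n, n_regions = cfg$n_regions,
                           clusters_per_region = cfg$clusters, seed = seed)
  sim <- simulate_underweight(scenario)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(data = file.path(dir, "data.csv"),
             adjacency = file.path(dir, "adjacency.txt"),
             truth = file.path(dir, "truth.json"),
             scenario = file.path(dir, "scenario.json"))
  readr::write_csv(sim$data, paths["data"])
  write_adjacency(sim$adjacency, paths["adjacency"])
  jsonlite::write_json(
    list(spatial = sim$truth$spatial, smooth = sim$truth$smooth,
         gamma = as.list(sim$truth$gamma), sigma = sim$truth$sigma),
    paths["truth"], digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    list(size = size, n = cfg$n, n_regions = cfg$n_regions,
         clusters_per_region = cfg$clusters, seed = seed,
         tau_spat = scenario$tau_spat, sigma = scenario$sigma,
         cat_probs = lapply(scenario$cat_probs, as.list)),
    paths["scenario"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
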