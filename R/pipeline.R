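#' Run the full underweight analysis pipeline from one configuration
#'
#' Orchestrates the complete workflow on a child-level dataset:
#' validation and complete-case filtering, Yeo-Johnson binned screening
#' profiles and the response density check, design assembly, Gibbs
#' sampling, posterior summary tables (fixed effects, smoothing variances,
#' scale), smooth-effect curves with 80/95% bands, DIC, MCMC and residual
#' diagnostics, the spatial-effect surface, the residual spatial pattern,
#' and IDW hotspot interpolation. Every artefact is written as CSV/JSON
#' into `output_dir`, and a `manifest.json` records the configuration, its
#' hash, the seed, package version, per-stage row counts and timings — the
#' manifest alone suffices to reproduce the run. On a stage failure the
#' outputs produced so far are retained and the manifest marks the failed
#' stage.
#'
#' @param config A named list, or a path to a YAML/JSON file holding one.
#'   Recognized fields: `data` (CSV path or data frame), `adjacency` (edge
#'   list path or data frame), `columns` (list: `response`, `smooth`,
#'   `fixed`, `spatial`, `lon`, `lat`), `priors`, `mcmc` (`iterations`,
#'   `burnin`, `thin`), `idw` (`power`, `n_lon`, `n_lat`, `prob`, `by`),
#'   `screening` (`n_bins`, `transform`), `output_dir`, `seed`.
#' @return Invisibly, a list with the `fit`, the output `dir`, and the
#'   `manifest` list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("[.]json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cols <- config$columns %||% list()
  response <- cols$response %||% "waz"
  smooth <- unlist(cols$smooth %||% c("child_age", "mother_age", "mother_bmi"))
  fixed <- unlist(cols$fixed %||% character())
  spatial <- cols$spatial
  seed <- as.integer(config$seed %||% 1L)
  dir <- config$output_dir %||% tempfile("geowaz_run_")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    package = "geowaz",
    version = as.character(utils::packageVersion("geowaz")),
    seed = seed,
    config = config[setdiff(names(config), "data")],
    config_hash = rlang::hash(config[setdiff(names(config), "data")]),
    stages = list(), status = "running"
  )
  state <- new.env(parent = emptyenv())
  finish <- function(status) {
    manifest$status <<- status
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      finish(paste0("failed:", name))
      rlang::abort(sprintf("Pipeline stage `%s` failed: %s", name,
                           conditionMessage(e)), parent = e)
    })
    manifest$stages[[name]] <<- c(
      list(status = "ok",
           seconds = round(proc.time()[["elapsed"]] - t0, 3)),
      attr(res, "manifest_info") %||% list())
    res
  }

  data <- stage("load", {
    d <- config$data
    if (is.character(d)) d <- readr::read_csv(d, show_col_types = FALSE)
    d <- tibble::as_tibble(d)
    for (f in fixed) if (!is.factor(d[[f]])) d[[f]] <- factor(d[[f]])
    structure(d, manifest_info = list(rows = nrow(d)))
  })
  adjacency <- stage("adjacency", {
    a <- config$adjacency
    if (is.character(a)) a <- read_adjacency(a)
    if (!is.null(a)) a <- tibble::as_tibble(as.data.frame(a)[1:2],
                                            .name_repair = ~ c("from", "to"))
    if (!is.null(a)) write_adjacency(a, file.path(dir, "adjacency_used.txt"))
    a
  })

  stage("screening", {
    scr <- config$screening %||% list()
    profiles <- purrr::map_dfr(smooth, function(nm) {
      dplyr::mutate(
        binned_profile(data[stats::complete.cases(data[c(nm, response)]), ],
                       nm, response,
                       n_bins = scr$n_bins %||% 30,
                       transform = scr$transform %||% "none"),
        term = nm, .before = 1)
    })
    readr::write_csv(profiles, file.path(dir, "screening_profiles.csv"))
    dens <- density_profile(data[[response]][is.finite(data[[response]])])
    readr::write_csv(dens$density, file.path(dir, "response_density.csv"))
    structure(profiles, manifest_info = list(rows = nrow(profiles)))
  })

  design <- stage("design", {
    d <- build_design(data, response = response, fixed = fixed,
                      smooth = smooth, spatial = spatial,
                      adjacency = adjacency)
    structure(d, manifest_info = list(rows_used = length(d$y),
                                      rows_dropped = d$n_dropped))
  })

  fit <- stage("gibbs", {
    pr <- do.call(prior_control, config$priors %||% list())
    mc <- config$mcmc %||% list()
    ctl <- mcmc_control(iterations = mc$iterations %||% 12000,
                        burnin = mc$burnin %||% 2000,
                        thin = mc$thin %||% 10, seed = seed)
    f <- fit_geoadditive(design, priors = pr, control = ctl)
    structure(f, manifest_info = list(draws = f$n_draws))
  })

  stage("summaries", {
    readr::write_csv(tidy(fit, "fixed"), file.path(dir, "fixed_effects.csv"))
    readr::write_csv(tidy(fit, "smooth_variance"),
                     file.path(dir, "smooth_variances.csv"))
    readr::write_csv(tidy(fit, "scale"), file.path(dir, "scale_estimate.csv"))
    readr::write_csv(smooth_effects(fit), file.path(dir, "smooth_effects.csv"))
    invisible(NULL)
  })

  stage("dic", {
    dic <- compute_dic(fit)
    jsonlite::write_json(unclass(dic), file.path(dir, "dic.json"),
                         auto_unbox = TRUE, digits = NA)
    dic
  })

  stage("diagnostics", {
    readr::write_csv(max_autocorrelation(fit, lags = min(20, fit$n_draws - 1)),
                     file.path(dir, "max_autocorrelation.csv"))
    readr::write_csv(residual_diagnostics(fit),
                     file.path(dir, "residual_diagnostics.csv"))
    invisible(NULL)
  })

  if (!is.null(spatial)) {
    stage("spatial", {
      readr::write_csv(spatial_effect_surface(fit),
                       file.path(dir, "spatial_effects.csv"))
      readr::write_csv(residual_spatial_pattern(fit),
                       file.path(dir, "residual_spatial.csv"))
      invisible(NULL)
    })
    has_coords <- all(c(cols$lon %||% "lon", cols$lat %||% "lat") %in%
                        names(data))
    if (has_coords) {
      stage("idw", {
        iw <- config$idw %||% list()
        src <- predict_severity_sources(fit, by = iw$by %||% "cluster")
        grid <- idw_interpolate(src,
                                grid = list(n_lon = iw$n_lon %||% 50,
                                            n_lat = iw$n_lat %||% 50),
                                power = iw$power %||% 2)
        hs <- hotspot_classify(grid, prob = iw$prob %||% 0.8)
        readr::write_csv(src, file.path(dir, "idw_sources.csv"))
        readr::write_csv(hs, file.path(dir, "idw_grid.csv"))
        structure(hs, manifest_info = list(
          grid_cells = nrow(hs), hotspots = sum(hs$hotspot)))
      })
    }
  }

  finish("ok")
  invisible(list(fit = fit, dir = dir, manifest = manifest))
}
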