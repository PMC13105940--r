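#' Posterior spatial-effect surface
#'
#' Per-region posterior summaries of the structured spatial effect with the
#' three-class credible-interval significance used on spatial maps: regions
#' whose 95% interval lies above zero are `"positive"` (higher WAZ, less
#' underweight), below zero `"negative"`, else `"null"`. The effect is
#' centred on zero across regions; the overall level sits in the intercept.
#'
#' @param fit A `geowaz_fit` with a spatial term.
#' @return A tibble: `region`, `mean`, `sd`, `q2.5`, `q10`, `q50`, `q90`,
#'   `q97.5`, `significance`.
#' @export
spatial_effect_surface <- function(fit) {
  stopifnot(inherits(fit, "geowaz_fit"))
  if (is.null(fit$fspat)) stop_geowaz("Model has no spatial term.", "validation")
  tidy(fit, "spatial")
}

#' Region-wise mean residual surface
#'
#' Averages posterior-mean residuals within each region — the residual
#' spatial pattern left after the model's covariates and structured spatial
#' effect. Regions holding fewer than `min_count` observations are flagged
#' as unreliable.
#'
#' @param fit A `geowaz_fit`.
#' @param region_col Column of the design data holding region labels; only
#'   needed when the model itself has no spatial term.
#' @param min_count Minimum observations per region (default 10).
#' @return A tibble: `region`, `mean_residual`, `count`, `flagged`.
#' @export
residual_spatial_pattern <- function(fit, region_col = NULL, min_count = 10) {
  stopifnot(inherits(fit, "geowaz_fit"))
  if (!is.null(fit$design$region_index)) {
    regions <- fit$design$mrf$regions
    region_index <- fit$design$region_index
  } else if (!is.null(region_col)) {
    obs <- as.character(fit$design$data[[region_col]])
    regions <- sort(unique(obs))
    region_index <- match(obs, regions)
  } else {
    stop_geowaz("Model has no region mapping; supply `region_col`.",
                "validation")
  }
  r <- fit$design$y - fit$eta_bar
  idx <- factor(region_index, levels = seq_along(regions))
  out <- tibble::tibble(
    region = regions,
    mean_residual = as.vector(tapply(r, idx, mean, default = NA_real_)),
    count = as.vector(table(idx))
  )
  out$flagged <- out$count < min_count
  out
}

#' Inverse-distance-weighted interpolation
#'
#' Interpolates source values onto a grid of lon/lat points with IDW
#' weights \eqn{w_i = d_i^{-p}} on great-circle (haversine) distances in
#' km. A grid point coinciding with a source returns that source's value
#' exactly; duplicate source locations with conflicting values are averaged
#' with a warning. Interpolated values always lie within the range of the
#' source values, and the interpolation commutes with adding a constant to
#' all source values.
#'
#' @param sources A data frame with columns `lon`, `lat`, `value`.
#' @param grid Either a data frame of `lon`, `lat` points, or a list
#'   `list(n_lon =, n_lat =, bbox = c(lon_min, lat_min, lon_max, lat_max))`;
#'   `bbox` defaults to the source bounding box.
#' @param power IDW power `p > 0` (default 2).
#' @return An object of class `geowaz_idw`: a tibble `lon`, `lat`, `value`
#'   with attributes `power` and `sources`.
#' @export
idw_interpolate <- function(sources, grid = list(n_lon = 50, n_lat = 50),
                            power = 2) {
  sources <- tibble::as_tibble(sources)
  for (col in c("lon", "lat", "value")) {
    if (!col %in% names(sources)) {
      stop_geowaz(sprintf("`sources` needs a `%s` column.", col), "validation")
    }
    check_finite(sources[[col]], col)
  }
  if (nrow(sources) < 1) stop_geowaz("Need at least one source.", "validation")
  if (!is.numeric(power) || length(power) != 1 || power <= 0) {
    stop_geowaz("`power` must be a positive scalar.", "validation")
  }
  key <- paste(sources$lon, sources$lat, sep = "/")
  if (anyDuplicated(key) > 0) {
    dup_conflict <- any(tapply(sources$value, key, function(v) length(unique(v)) > 1))
    if (dup_conflict) {
      rlang::warn("Duplicate source locations with conflicting values; averaging.")
    }
    sources <- dplyr::summarise(dplyr::group_by(sources, .data$lon, .data$lat),
                                value = mean(.data$value), .groups = "drop")
  }
  if (is.data.frame(grid)) {
    pts <- tibble::as_tibble(grid[c("lon", "lat")])
  } else {
    bbox <- grid$bbox %||% c(min(sources$lon), min(sources$lat),
                             max(sources$lon), max(sources$lat))
    pts <- tidyr::expand_grid(
      lon = seq(bbox[1], bbox[3], length.out = grid$n_lon %||% 50),
      lat = seq(bbox[2], bbox[4], length.out = grid$n_lat %||% 50))
  }
  src_mat <- cbind(sources$lon, sources$lat)
  vals <- vapply(seq_len(nrow(pts)), function(i) {
    d <- geosphere::distHaversine(c(pts$lon[i], pts$lat[i]), src_mat) / 1000
    hit <- which(d == 0)
    if (length(hit) > 0) return(sources$value[hit[1]])
    w <- d^(-power)
    sum(w * sources$value) / sum(w)
  }, numeric(1))
  structure(tibble::tibble(lon = pts$lon, lat = pts$lat, value = vals),
            power = power, sources = sources,
            class = c("geowaz_idw", class(tibble::tibble())))
}

#' Hotspot classification on an interpolated surface
#'
#' Flags grid cells whose interpolated underweight severity *strictly*
#' exceeds a quantile of the grid values. The default threshold (worst
#' quintile, `prob = 0.8`) is a mapping convention, not an epidemiological
#' cut-off. Severity should be oriented so that larger = worse (see
#' [predict_severity_sources()]).
#'
#' @param grid A `geowaz_idw` tibble (or any tibble with a `value` column).
#' @param prob Quantile defining the threshold (default 0.8).
#' @return The grid tibble with logical `hotspot` and the numeric
#'   `threshold` as an attribute.
#' @export
hotspot_classify <- function(grid, prob = 0.8) {
  if (!"value" %in% names(grid)) {
    stop_geowaz("`grid` needs a `value` column.", "validation")
  }
  if (prob <= 0 || prob >= 1) stop_geowaz("`prob` must be in (0,1).", "validation")
  thr <- quantile(grid$value, probs = prob, type = 7, names = FALSE)
  out <- dplyr::mutate(tibble::as_tibble(grid), hotspot = .data$value > thr)
  attr(out, "threshold") <- thr
  out
}

#' Cluster-level predicted severity for hotspot interpolation
#'
#' Builds the IDW source table from a fitted model: the posterior-mean
#' predicted WAZ is averaged per sampling cluster (or per region centroid)
#' and its sign flipped so that larger values mean more severe predicted
#' underweight.
#'
#' @param fit A `geowaz_fit` whose design data contain `lon` and `lat`
#'   columns (cluster coordinates).
#' @param by `"cluster"` (default; unique coordinate pairs) or `"region"`
#'   (region centroids of the observed clusters).
#' @return A tibble `lon`, `lat`, `value` (predicted severity) ready for
#'   [idw_interpolate()].
#' @export
predict_severity_sources <- function(fit, by = c("cluster", "region")) {
  by <- match.arg(by)
  dat <- fit$design$data
  if (!all(c("lon", "lat") %in% names(dat))) {
    stop_geowaz("Design data lack `lon`/`lat` coordinates.", "validation")
  }
  base <- tibble::tibble(lon = dat$lon, lat = dat$lat,
                         severity = -fit$eta_bar)
  if (by == "cluster") {
    dplyr::summarise(dplyr::group_by(base, .data$lon, .data$lat),
                     value = mean(.data$severity), .groups = "drop")
  } else {
    base$region <- fit$design$mrf$regions[fit$design$region_index]
    dplyr::summarise(dplyr::group_by(base, .data$region),
                     lon = mean(.data$lon), lat = mean(.data$lat),
                     value = mean(.data$severity), .groups = "drop")[
                       , c("lon", "lat", "value")]
  }
}
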