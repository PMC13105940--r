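#' B-spline basis with equidistant knots
#'
#' Evaluates a B-spline basis for a metrical covariate on equidistant knots
#' spanning `[min(x), max(x)]`, extended by `degree` knots on each side so
#' that the basis is a partition of unity over the whole covariate range
#' (every row of the basis matrix sums to one and all entries are
#' non-negative). Together with a difference penalty on the coefficients
#' this is the P-spline representation of a smooth term.
#'
#' @param x Numeric covariate vector with at least two distinct values.
#' @param degree Spline degree (default 3, cubic).
#' @param n_knots Number of interior knots (default 20). The basis has
#'   `n_knots + degree + 1` columns.
#' @param penalty_order Order of the difference penalty attached to the
#'   term (default 2, a second-order random walk).
#' @param range Optional length-2 numeric giving the knot span; defaults to
#'   `range(x)`. Supply it to evaluate an existing basis at new points.
#' @return An object of class `geowaz_spline`: a list with `B` (n x m basis
#'   matrix), `knots` (full extended knot vector), `K` (m x m penalty
#'   matrix), `penalty_order`, `penalty_rank` (`m - penalty_order`),
#'   `degree`, and `range`.
#' @examples
#' sb <- bspline_basis(runif(50, 0, 59))
#' range(rowSums(sb$B)) # all 1
#' @export
bspline_basis <- function(x, degree = 3, n_knots = 20, penalty_order = 2,
                          range = NULL) {
  check_finite(x, "x")
  degree <- check_scalar_count(degree, "degree", min = 1L)
  n_knots <- check_scalar_count(n_knots, "n_knots", min = 1L)
  rng <- range %||% base::range(x)
  if (diff(rng) <= 0) {
    stop_geowaz("Covariate is constant: cannot build a spline basis.",
                "degenerate_covariate")
  }
  inner <- seq(rng[1], rng[2], length.out = n_knots + 2)
  h <- inner[2] - inner[1]
  knots <- c(rng[1] - h * (degree:1), inner, rng[2] + h * (1:degree))
  B <- splines::splineDesign(knots, x, ord = degree + 1, outer.ok = FALSE)
  m <- ncol(B)
  K <- difference_penalty(m, penalty_order)
  structure(
    list(B = B, knots = knots, K = K, penalty_order = penalty_order,
         penalty_rank = m - penalty_order, degree = degree, range = rng),
    class = "geowaz_spline"
  )
}

#' Difference penalty matrix for P-spline coefficients
#'
#' Builds `K = t(D) %*% D` where `D` is the order-`d` difference operator on
#' `m` coefficients. `K` is symmetric positive semidefinite with rank
#' `m - d`; its null space is spanned by polynomial coefficient sequences of
#' degree `d - 1`, so e.g. the default second-order penalty leaves straight
#' lines unpenalized.
#'
#' @param m Number of basis coefficients.
#' @param d Difference order, `1 <= d < m`.
#' @return An `m x m` penalty matrix.
#' @export
difference_penalty <- function(m, d = 2) {
  m <- check_scalar_count(m, "m", min = 2L)
  d <- check_scalar_count(d, "d", min = 1L)
  if (m <= d) {
    stop_geowaz("Penalty order `d` must be smaller than the basis size `m`.",
                "invalid_order")
  }
  D <- diff(diag(m), differences = d)
  crossprod(D)
}

#' Intrinsic Markov-random-field precision from region adjacency
#'
#' Builds the intrinsic (improper) MRF precision matrix over regions:
#' diagonal entries are neighbour counts, off-diagonal entries are -1 for
#' adjacent region pairs and 0 otherwise. Rows sum to zero and the rank is
#' `S - c` where `c` is the number of connected components; the implied
#' prior penalizes the sum of squared differences between adjacent regions
#' and is invariant to component-wise level shifts.
#'
#' Regions with no neighbours ("islands") destabilize identification (each
#' adds an improper dimension), so by default an island is connected to its
#' nearest region by centroid distance, with a warning; supply
#' `island_action = "keep"` to retain it unlinked.
#'
#' @param adjacency A data frame / two-column matrix of undirected edges
#'   (region labels), or `NULL` for no edges.
#' @param regions Character vector of all region labels (defaults to those
#'   appearing in `adjacency`).
#' @param centroids Optional tibble `region`, `lon`, `lat` used for island
#'   linking.
#' @param island_action `"link"` (default) or `"keep"`.
#' @return An object of class `geowaz_mrf`: list with `regions`, `edges`
#'   (tibble `from`, `to`), `K` (S x S precision with dimnames), and
#'   `n_components`.
#' @export
mrf_precision <- function(adjacency, regions = NULL, centroids = NULL,
                          island_action = c("link", "keep")) {
  island_action <- match.arg(island_action)
  edges <- if (is.null(adjacency) || NROW(adjacency) == 0) {
    tibble::tibble(from = character(), to = character())
  } else {
    adjacency <- as.data.frame(adjacency)
    tibble::tibble(from = as.character(adjacency[[1]]),
                   to = as.character(adjacency[[2]]))
  }
  regions <- as.character(regions %||% sort(unique(c(edges$from, edges$to))))
  if (length(regions) < 1) stop_geowaz("No regions given.", "validation")
  unknown <- setdiff(c(edges$from, edges$to), regions)
  if (length(unknown) > 0) {
    stop_geowaz(paste0("Edges reference unknown regions: ",
                       paste(unique(unknown), collapse = ", ")), "validation")
  }
  edges <- dplyr::filter(edges, .data$from != .data$to) # drop self-loops
  # canonical undirected form, deduplicated
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges <- dplyr::distinct(edges)

  deg <- table(factor(c(edges$from, edges$to), levels = regions))
  islands <- regions[deg == 0]
  if (length(islands) > 0 && length(regions) > 1 && island_action == "link") {
    for (isl in islands) {
      other <- setdiff(regions, isl)
      nearest <- if (!is.null(centroids)) {
        ci <- centroids[match(isl, centroids$region), ]
        co <- centroids[match(other, centroids$region), ]
        other[which.min(geosphere::distHaversine(
          c(ci$lon, ci$lat), cbind(co$lon, co$lat)))]
      } else {
        other[1]
      }
      rlang::warn(sprintf(
        "Region '%s' has no neighbours; linking it to '%s'.", isl, nearest),
        class = "geowaz_warning_island")
      e <- sort(c(isl, nearest))
      edges <- dplyr::distinct(dplyr::bind_rows(
        edges, tibble::tibble(from = e[1], to = e[2])))
    }
  }

  S <- length(regions)
  K <- matrix(0, S, S, dimnames = list(regions, regions))
  if (nrow(edges) > 0) {
    i <- match(edges$from, regions)
    j <- match(edges$to, regions)
    for (e in seq_along(i)) {
      K[i[e], j[e]] <- K[i[e], j[e]] - 1
      K[j[e], i[e]] <- K[j[e], i[e]] - 1
      K[i[e], i[e]] <- K[i[e], i[e]] + 1
      K[j[e], j[e]] <- K[j[e], j[e]] + 1
    }
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = regions))
  structure(
    list(regions = regions, edges = edges, K = K,
         n_components = igraph::components(g)$no),
    class = "geowaz_mrf"
  )
}

#' Read or write a region adjacency edge list
#'
#' Plain two-column whitespace/comma-separated text, one undirected edge per
#' line. Writing the derived adjacency out keeps runs reproducible.
#'
#' @param path File path.
#' @return `read_adjacency()` returns a tibble `from`, `to`.
#' @export
read_adjacency <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("from", "to"),
                          colClasses = "character")
  tibble::as_tibble(df)
}

#' @param edges A tibble/data frame of edges (`from`, `to`).
#' @rdname read_adjacency
#' @export
write_adjacency <- function(edges, path) {
  readr::write_delim(dplyr::select(as.data.frame(edges), 1:2), path,
                     delim = " ", col_names = FALSE)
  invisible(path)
}

#' Assemble design blocks for a geoadditive model
#'
#' Constructs all matrices the Gibbs sampler consumes: the fixed-effects
#' matrix `W` (treatment/dummy coding against each factor's reference level,
#' with intercept), one P-spline block per smooth term, and the one-hot
#' region incidence for the spatial term. Rows with missing values in any
#' model variable are dropped (complete-case filter) with a message giving
#' the count.
#'
#' @param data A data frame of child-level records.
#' @param response Column name of the Gaussian response (e.g. WAZ).
#' @param fixed Character vector of categorical/linear fixed-effect columns.
#' @param smooth Character vector of metrical covariate columns to model
#'   with P-splines, or a named list of per-term options
#'   (`degree`, `n_knots`, `penalty_order`).
#' @param spatial Column name of the region label, or `NULL` for no spatial
#'   term.
#' @param adjacency Edge list (data frame `from`, `to`) or a `geowaz_mrf`
#'   object; required when `spatial` is given.
#' @param degree,n_knots,penalty_order Defaults applied to every smooth
#'   term without per-term options.
#' @return An object of class `geowaz_design`: list with `y`, `W` (with
#'   column names), `smooths` (named list of `geowaz_spline`), `region_index`
#'   (integer vector into `mrf$regions`), `mrf`, `term_labels`, `data`
#'   (the filtered tibble), `n_dropped`.
#' @export
build_design <- function(data, response, fixed = character(), smooth = character(),
                         spatial = NULL, adjacency = NULL,
                         degree = 3, n_knots = 20, penalty_order = 2) {
  data <- tibble::as_tibble(data)
  smooth_opts <- if (is.list(smooth)) smooth else
    setNames(rep(list(list()), length(smooth)), smooth)
  vars <- c(response, fixed, names(smooth_opts), spatial)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    stop_geowaz(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")),
                "validation")
  }
  cc <- stats::complete.cases(data[vars])
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    rlang::inform(sprintf("Complete-case filter dropped %d of %d rows.",
                          n_dropped, nrow(data)))
  }
  data <- data[cc, , drop = FALSE]
  if (nrow(data) == 0) stop_geowaz("No complete rows remain.", "validation")
  y <- data[[response]]
  check_finite(y, response)

  # fixed effects: treatment coding, intercept first
  if (length(fixed) > 0) {
    fml <- stats::reformulate(sprintf("`%s`", fixed))
    W <- model.matrix(fml, data = data)
  } else {
    W <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  }
  qr_w <- qr(W)
  if (qr_w$rank < ncol(W)) {
    bad <- colnames(W)[qr_w$pivot[(qr_w$rank + 1):ncol(W)]]
    stop_geowaz(paste0("Fixed-effects matrix is rank deficient; offending ",
                       "columns: ", paste(bad, collapse = ", ")), "collinearity")
  }

  smooths <- purrr::imap(smooth_opts, function(opts, nm) {
    bspline_basis(data[[nm]],
                  degree = opts$degree %||% degree,
                  n_knots = opts$n_knots %||% n_knots,
                  penalty_order = opts$penalty_order %||% penalty_order)
  })

  mrf <- NULL
  region_index <- NULL
  if (!is.null(spatial)) {
    if (is.null(adjacency)) {
      stop_geowaz("A spatial term needs an `adjacency` edge list.", "validation")
    }
    obs_regions <- as.character(data[[spatial]])
    mrf <- if (inherits(adjacency, "geowaz_mrf")) adjacency else
      mrf_precision(adjacency, regions = sort(unique(c(
        obs_regions,
        as.character(unlist(as.data.frame(adjacency)[1:2]))))))
    if (!all(obs_regions %in% mrf$regions)) {
      stop_geowaz("Some observations map to regions absent from the adjacency.",
                  "validation")
    }
    region_index <- match(obs_regions, mrf$regions)
  }

  structure(
    list(y = y, W = W, smooths = smooths, region_index = region_index,
         mrf = mrf, response = response, fixed = fixed,
         spatial = spatial,
         term_labels = c(colnames(W), paste0("sx(", names(smooths), ")"),
                         if (!is.null(mrf)) paste0("sx(", spatial, ")")),
         data = data, n_dropped = n_dropped),
    class = "geowaz_design"
  )
}

#' @export
print.geowaz_design <- function(x, ...) {
  cat(sprintf("geoadditive design: n = %d, %d fixed-effect columns, %d smooth term(s)%s\n",
              length(x$y), ncol(x$W), length(x$smooths),
              if (!is.null(x$mrf)) sprintf(", spatial MRF over %d regions",
                                           length(x$mrf$regions)) else ""))
  invisible(x)
}
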