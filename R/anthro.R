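#' Anthropometric z-scores and underweight classification
#'
#' `compute_zscore()` standardizes an individual anthropometric index `ai`
#' (e.g. weight at a given age) against a reference population median `mi`
#' and standard deviation `sd`, returning `(ai - mi) / sd`.
#' `classify_underweight()` applies the WHO convention for weight-for-age:
#' a child is underweight when the z-score lies strictly below -2.
#'
#' The z-score boundary is strict: a WAZ of exactly -2 is *not* classified
#' as underweight.
#'
#' @param ai Numeric vector of individual index values.
#' @param mi Numeric vector of reference medians (same units as `ai`).
#' @param sd Numeric vector of reference standard deviations; all must be
#'   strictly positive.
#' @return `compute_zscore()` returns a numeric vector of dimensionless
#'   z-scores; `classify_underweight()` a logical vector.
#' @examples
#' compute_zscore(11.3, 10.1, 0.8)
#' classify_underweight(c(-2.01, -2, 0.4))
#' @export
compute_zscore <- function(ai, mi, sd) {
  check_finite(ai, "ai")
  check_finite(mi, "mi")
  if (!is.numeric(sd) || anyNA(sd) || any(!is.finite(sd))) {
    stop_geowaz("`sd` must be finite and non-missing.", "validation")
  }
  if (any(sd <= 0)) {
    stop_geowaz("Reference standard deviations must be strictly positive.",
                "invalid_reference")
  }
  (ai - mi) / sd
}

#' @param z Numeric vector of z-scores.
#' @rdname compute_zscore
#' @export
classify_underweight <- function(z) {
  check_finite(z, "z")
  z < -2
}

#' Read an anthropometric reference table
#'
#' Reads a CSV with columns `stratum_age_months`, `sex`, `median`, `sd`, one
#' row per age-by-sex stratum. Strata must be unique and every `sd` strictly
#' positive. The package does not bundle WHO Child Growth Standards values;
#' supply your own extract in this layout.
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per stratum.
#' @export
read_anthro_reference <- function(path) {
  ref <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("stratum_age_months", "sex", "median", "sd")
  missing <- setdiff(needed, names(ref))
  if (length(missing) > 0) {
    stop_geowaz(paste0("Reference table lacks columns: ",
                       paste(missing, collapse = ", ")), "validation")
  }
  if (any(!is.finite(ref$sd)) || any(ref$sd <= 0)) {
    stop_geowaz("Reference `sd` must be finite and strictly positive.",
                "invalid_reference")
  }
  if (anyDuplicated(ref[c("stratum_age_months", "sex")]) > 0) {
    stop_geowaz("Reference strata (age x sex) must be unique.", "validation")
  }
  tibble::as_tibble(ref)
}

#' Attach z-scores and underweight flags to child records
#'
#' Optional pre-processing stage: joins a reference table onto child-level
#' data by age-in-months and sex and adds `waz` and `underweight` columns.
#' The main modelling pipeline accepts WAZ directly (as DHS datasets provide
#' it); use this only when z-scores must be recomputed from raw weights.
#'
#' @param data A data frame of child records.
#' @param reference A reference tibble as returned by
#'   [read_anthro_reference()].
#' @param weight,age,sex Column names (strings) in `data` holding the raw
#'   index value, age in completed months, and sex (levels matching the
#'   reference `sex` column).
#' @return `data` as a tibble with `waz` and `underweight` columns appended.
#' @export
add_anthro <- function(data, reference, weight = "weight", age = "age_months",
                       sex = "sex") {
  for (col in c(weight, age, sex)) {
    if (!col %in% names(data)) {
      stop_geowaz(sprintf("Column `%s` not found in `data`.", col), "validation")
    }
  }
  out <- dplyr::left_join(
    tibble::as_tibble(data),
    dplyr::rename(reference,
                  "{age}" := "stratum_age_months", "{sex}" := "sex"),
    by = c(age, sex)
  )
  if (anyNA(out$median) || anyNA(out$sd)) {
    stop_geowaz("Some records have no matching reference stratum.", "validation")
  }
  out$waz <- compute_zscore(out[[weight]], out$median, out$sd)
  out$underweight <- classify_underweight(out$waz)
  dplyr::select(out, -"median", -"sd")
}
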