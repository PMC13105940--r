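# Internal validation helpers. Error classes follow rlang conventions so
# callers can condition on them (`geowaz_error_*`).

stop_geowaz <- function(msg, class, ...) {
  rlang::abort(msg, class = c(paste0("geowaz_error_", class), "geowaz_error"), ...)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_geowaz(sprintf("`%s` must be finite and non-missing.", name), "validation")
  }
  invisible(x)
}

check_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    stop_geowaz(sprintf("`%s` must be a single integer >= %d.", name, min), "validation")
  }
  invisible(as.integer(x))
}

# Draw from InverseGamma(shape, scale): density ~ x^{-shape-1} exp(-scale/x)
rinvgamma <- function(n, shape, scale) {
  1 / rgamma(n, shape = shape, rate = scale)
}

# Quantile labels like "q2.5", "q50", "q97.5"
quantile_labels <- function(probs) {
  paste0("q", formatC(100 * probs, format = "fg"))
}
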