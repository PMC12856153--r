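# Small shared helpers: rounding, truncated draws, argument checks.

#' Round half away from zero
#'
#' Rounds to the nearest integer (or decimal) with halves always rounded up,
#' matching how the published incidence tables are rounded, rather than R's
#' default round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 46.189))
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Inverse-CDF truncated-normal draw from supplied uniforms, so cohort
# generation stays reproducible under the per-participant draw layout.
qtruncnorm <- function(u, mean, sd, lower = -Inf, upper = Inf) {
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pa + u * (pb - pa), mean, sd)
}

# stop() with the calling function's name stripped, for cleaner messages
fail <- function(...) stop(..., call. = FALSE)

check_numeric_range <- function(x, name, lower, upper, allow_na = FALSE) {
  if (!is.numeric(x)) {
    fail(sprintf("'%s' must be numeric", name))
  }
  bad <- !is.na(x) & (!is.finite(x) | x < lower | x > upper)
  if (any(bad)) {
    fail(sprintf(
      "'%s' out of range [%s, %s]: first offending value %s",
      name, format(lower), format(upper), format(x[!is.na(x) & bad][1])
    ))
  }
  if (!allow_na && anyNA(x)) {
    fail(sprintf("'%s' contains missing values", name))
  }
  invisible(x)
}

check_flag <- function(x, name, n = length(x)) {
  if (is.numeric(x) && all(x %in% c(0, 1))) x <- as.logical(x)
  if (!is.logical(x) || anyNA(x)) {
    fail(sprintf("'%s' must be logical (TRUE/FALSE) without missing values", name))
  }
  if (length(x) == 1) x <- rep(x, n)
  if (length(x) != n) fail(sprintf("'%s' has length %d, expected %d", name, length(x), n))
  x
}

DAYS_PER_YEAR <- 365.25
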