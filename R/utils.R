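#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published summary tables round
#' half up, so percentages formatted for reports use this variant.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a count ratio as a table-style percentage
#'
#' Computes `100 * numerator / denominator` rounded half-up to one decimal,
#' or to two decimals when the percentage is below 0.05 (so small fractions
#' keep a significant figure, as in published comparison tables).
#'
#' @param numerator,denominator Non-negative counts.
#' @return Percentage on the 0-100 scale.
#' @export
pct_of <- function(numerator, denominator) {
  stopifnot(denominator > 0, numerator >= 0)
  p <- 100 * numerator / denominator
  ifelse(p < 0.05, round_half_up(p, 2), round_half_up(p, 1))
}

## internal parameter checks -------------------------------------------------

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (integerish && x != round(x)) {
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## near-constant detection: columns whose variation is at rounding-noise
## level relative to their magnitude carry no usable information
is_constant_col <- function(x, tol = 1e-8) {
  stats::sd(x) <= tol * (1 + abs(mean(x)))
}
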