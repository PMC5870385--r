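`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Deterministic "half-up" rounding used for all comparisons against printed
#' percentages and kappa values, where base R's banker's rounding would give
#' e.g. `round(0.5) == 0`.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
#' @examples
#' round_half_up(c(0.125, -0.125), 2)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small guard absorbs binary representation error in x * p (e.g. 0.105 * 100)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# proportion -> percentage at 1 d.p. printed precision
as_pct <- function(x, digits = 1) round_half_up(100 * x, digits)
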