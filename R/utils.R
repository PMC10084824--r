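#' Round half away from zero at a fixed number of decimals
#'
#' Commercial ("half-up") rounding, used everywhere a percentage is printed:
#' 98.4875 rounds to 98.49, -0.005 rounds to -0.01. Base [round()] rounds half
#' to even, which does not reproduce published metric tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return `x` rounded half away from zero at `digits` decimals.
#' @export
#' @examples
#' round_half_up(98.485)   # 98.49
#' round_half_up(2.5, 0)   # 3
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # 1e-9 guard absorbs binary representation error in values such as x.xx5
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## clip a vector (or matrix) to box bounds, recycling bounds over columns
clip_to_bounds <- function(x, lower, upper) {
  pmin(pmax(x, lower), upper)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## stop() with call. = FALSE everywhere; small wrapper keeps messages uniform
fail <- function(...) stop(..., call. = FALSE)
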