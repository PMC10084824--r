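#' One step of the logistic chaotic map
#'
#' The recurrence `x <- a * x * (1 - x)`. At the control value `a = 4` the map
#' is chaotic on (0, 1) and its iterates are ergodic with invariant density
#' `1 / (pi * sqrt(x * (1 - x)))` (mean 1/2). The optimizer uses this sequence
#' in place of uniform draws when building its initial population and to drive
#' the perturbation-scale schedule: the sequence is deterministic, covers the
#' unit interval densely, and never repeats.
#'
#' Seeds 0, 0.25, 0.5 and 0.75 are forbidden at `a = 4`: their orbits collapse
#' onto the fixed points 0 or 0.75 within two steps.
#'
#' @param x current value in \[0, 1\].
#' @param a control parameter in (0, 4\]; chaos requires `a = 4`.
#' @return the next value `a * x * (1 - x)`.
#' @seealso [chaotic_sequence()] for a stateful stream of iterates.
#' @export
#' @examples
#' logistic_map_step(0.3, 4)   # 0.84
#' logistic_map_step(0.84, 4)  # 0.5376
logistic_map_step <- function(x, a = 4) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    fail("`x` must lie in [0, 1]")
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0 || a > 4)
    fail("`a` must lie in (0, 4]")
  a * x * (1 - x)
}

#' Create a logistic-map iterate stream
#'
#' Returns a closure producing successive logistic-map iterates. The seed is
#' drawn from the current RNG stream if not supplied, resampling until it
#' avoids the degenerate points \{0, 0.25, 0.5, 0.75\}.
#'
#' @param x0 starting value in (0, 1), not one of the forbidden seeds; drawn
#'   uniformly when `NULL`.
#' @param a control parameter, default 4 (chaotic regime).
#' @return a function `(n = 1)` returning the next `n` iterates.
#' @export
chaotic_sequence <- function(x0 = NULL, a = 4) {
  forbidden <- c(0, 0.25, 0.5, 0.75)
  if (is.null(x0)) {
    repeat {
      x0 <- stats::runif(1)
      if (min(abs(x0 - forbidden)) > 1e-9) break
    }
  }
  if (any(abs(x0 - forbidden) <= 1e-12))
    fail("`x0` must avoid {0, 0.25, 0.5, 0.75}")
  x <- x0
  function(n = 1L) {
    out <- numeric(n)
    for (k in seq_len(n)) {
      x <<- logistic_map_step(x, a)
      out[k] <- x
    }
    out
  }
}

#' Opposite point within box bounds
#'
#' Opposition-based ("reverse") learning evaluates the bound-reflected point
#' `lower + upper - x` alongside `x` and keeps the better of the two, which
#' diversifies a population at no modelling cost. The map is an involution:
#' applying it twice returns `x` exactly.
#'
#' @param x position vector.
#' @param lower,upper box bounds, same length as `x`.
#' @return the elementwise opposite point.
#' @export
#' @examples
#' opposite_point(2, 0, 10)  # 8
opposite_point <- function(x, lower, upper) {
  if (length(lower) != length(x) || length(upper) != length(x))
    fail("bounds must have the same length as `x`")
  lower + upper - x
}
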