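#' Classical benchmark test functions
#'
#' A small suite of standard continuous test functions used to validate the
#' optimizer: sphere, Rastrigin, Rosenbrock, Ackley and Griewank. All have
#' their global minimum value 0; sphere, Rastrigin, Ackley and Griewank attain
#' it at the origin, Rosenbrock at the all-ones vector.
#'
#' @param name one of `"sphere"`, `"rastrigin"`, `"rosenbrock"`, `"ackley"`,
#'   `"griewank"`.
#' @param x numeric vector, the evaluation point.
#' @return the function value, a finite scalar.
#' @export
#' @examples
#' benchmark_function("sphere", c(1, 1))     # 2
#' benchmark_function("rastrigin", c(0, 0))  # 0
benchmark_function <- function(name, x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    fail("`x` must be finite numeric")
  switch(match.arg(name, c("sphere", "rastrigin", "rosenbrock",
                           "ackley", "griewank")),
    sphere     = sum(x^2),
    rastrigin  = 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
    rosenbrock = {
      if (length(x) < 2) fail("rosenbrock needs dimension >= 2")
      i <- seq_len(length(x) - 1)
      sum(100 * (x[i + 1] - x[i]^2)^2 + (1 - x[i])^2)
    },
    ackley     = -20 * exp(-0.2 * sqrt(mean(x^2))) -
                 exp(mean(cos(2 * pi * x))) + 20 + exp(1),
    griewank   = 1 + sum(x^2) / 4000 -
                 prod(cos(x / sqrt(seq_along(x))))
  )
}

#' Benchmark suite with conventional search boxes
#'
#' @return a named list; each entry holds `fn` (a closure of `x`), `lower`,
#'   `upper` (scalar bounds, recycled over dimensions) and `minimum` (the
#'   global minimum value).
#' @export
benchmark_suite <- function() {
  mk <- function(name, lo, hi)
    list(fn = function(x) benchmark_function(name, x),
         lower = lo, upper = hi, minimum = 0)
  list(
    sphere     = mk("sphere",     -100,  100),
    rastrigin  = mk("rastrigin",  -5.12, 5.12),
    rosenbrock = mk("rosenbrock", -5,    10),
    ackley     = mk("ackley",     -32,   32),
    griewank   = mk("griewank",   -600,  600)
  )
}
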