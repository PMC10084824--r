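#' Control parameters for the chaotic Reptile Search optimizer
#'
#' Collects and validates every tunable of [erso()]. Defaults follow the
#' method's stated settings where it states them (`alpha = beta = 0.1`,
#' logistic-map control value 4) and documented package choices elsewhere.
#'
#' @param N population size (crocodiles), at least 2.
#' @param T_max iteration budget, at least 4 (the four behavioural phases each
#'   occupy a quarter of the budget).
#' @param alpha exploration control of the hunting-cooperation percentage
#'   difference; fixed at 0.1 in the method.
#' @param beta exploration control of the high-walking move; fixed at 0.1.
#' @param es_variant `"decaying"` (default) uses `2 * r3 * (1 - t/T)` so the
#'   evolutionary sense actually decays over iterations as its description
#'   requires; `"as_printed"` uses the constant-magnitude `2 * r3 * (1 - 1/T)`
#'   form. Both stay in \[-2, 2\].
#' @param epsilon_mode `"uniform"` draws the small stabiliser `e'` uniformly on
#'   \[0, 2\] at every use (the stated reading); `"fixed"` uses the constant
#'   `epsilon_fixed`.
#' @param epsilon_fixed constant used when `epsilon_mode = "fixed"`.
#' @param init `"chaotic_opposition"` (default) builds the initial population
#'   from logistic-map values plus their opposite points and keeps the better
#'   half; `"uniform"` is plain uniform initialization.
#' @param p_opp per-iteration probability of an opposition refresh of the
#'   worst candidate.
#' @param sigma_initial,sigma_final,sigma_exponent parameters of the decaying
#'   chaotic perturbation-scale schedule, see [sigma_schedule()].
#' @param perturb_prob per-candidate probability of a greedy Gaussian
#'   perturbation at scale `sigma_t` per iteration; 0 disables the step.
#' @param chaos_a logistic-map control parameter (4 for chaos).
#' @return a list of class `"erso_control"`.
#' @export
erso_control <- function(N = 30, T_max = 100, alpha = 0.1, beta = 0.1,
                         es_variant = c("decaying", "as_printed"),
                         epsilon_mode = c("uniform", "fixed"),
                         epsilon_fixed = 1e-10,
                         init = c("chaotic_opposition", "uniform"),
                         p_opp = 0.1,
                         sigma_initial = 1.0, sigma_final = 0.01,
                         sigma_exponent = 2, perturb_prob = 0.2,
                         chaos_a = 4) {
  es_variant <- match.arg(es_variant)
  epsilon_mode <- match.arg(epsilon_mode)
  init <- match.arg(init)
  if (N < 2) fail("`N` must be at least 2")
  if (T_max < 4) fail("`T_max` must be at least 4")
  if (alpha <= 0 || beta <= 0) fail("`alpha` and `beta` must be positive")
  if (sigma_initial < sigma_final || sigma_final < 0)
    fail("need sigma_initial >= sigma_final >= 0")
  if (p_opp < 0 || p_opp > 1) fail("`p_opp` must be in [0, 1]")
  if (perturb_prob < 0 || perturb_prob > 1)
    fail("`perturb_prob` must be in [0, 1]")
  structure(list(N = as.integer(N), T_max = as.integer(T_max),
                 alpha = alpha, beta = beta, es_variant = es_variant,
                 epsilon_mode = epsilon_mode, epsilon_fixed = epsilon_fixed,
                 init = init, p_opp = p_opp,
                 sigma_initial = sigma_initial, sigma_final = sigma_final,
                 sigma_exponent = sigma_exponent,
                 perturb_prob = perturb_prob, chaos_a = chaos_a),
            class = "erso_control")
}

## floor on denominator magnitude; preserves sign, warns once per optimizer run
guard_denominator <- function(den, floor = 1e-10, env = NULL) {
  small <- abs(den) < floor
  if (any(small)) {
    if (is.null(env) || !isTRUE(env$denominator_warned)) {
      warning("near-zero denominator guarded by floor 1e-10", call. = FALSE)
      if (!is.null(env)) env$denominator_warned <- TRUE
    }
    s <- sign(den[small])
    s[s == 0] <- 1
    den[small] <- s * floor
  }
  den
}

#' Percentage difference between a candidate coordinate and the best
#'
#' The hunting-cooperation driver
#' `P = alpha + (x_ij - avg_i) / (best_j * (upper_j - lower_j) + e')`,
#' where `avg_i` is the mean of candidate i's coordinates. The denominator is
#' floored at magnitude 1e-10.
#'
#' @param x_ij candidate coordinate.
#' @param avg mean of the candidate's coordinates.
#' @param best_j matching coordinate of the best solution.
#' @param lower_j,upper_j bounds of coordinate j.
#' @param alpha exploration control (default 0.1).
#' @param eps the stabiliser `e'`.
#' @return a scalar (vectorises over coordinates).
#' @export
#' @examples
#' rsa_percent_diff(1, 2, 2, 0, 10, alpha = 0.1, eps = 0.5)  # 0.1 - 1/20.5
rsa_percent_diff <- function(x_ij, avg, best_j, lower_j, upper_j,
                             alpha = 0.1, eps = 0) {
  den <- guard_denominator(best_j * (upper_j - lower_j) + eps)
  alpha + (x_ij - avg) / den
}

#' Hunting operator
#'
#' `eta = best_j * P`: the product of the best solution's coordinate and the
#' percentage difference [rsa_percent_diff()].
#'
#' @param best_j coordinate of the best solution.
#' @param P percentage difference.
#' @return `best_j * P`.
#' @export
rsa_hunting_eta <- function(best_j, P) best_j * P

#' Search-space reduce factor
#'
#' `R = (best_j - x_r2_j) / (best_j + e')` with `x_r2_j` the matching
#' coordinate of a randomly chosen candidate; shrinks the region explored by
#' the walking moves. Denominator floored at magnitude 1e-10.
#'
#' @param best_j coordinate of the best solution.
#' @param x_r2_j coordinate of a random candidate.
#' @param eps the stabiliser `e'`.
#' @return a scalar (vectorises).
#' @export
#' @examples
#' rsa_reduce_factor(1, 0, 1)  # 0.5
rsa_reduce_factor <- function(best_j, x_r2_j, eps = 0) {
  den <- guard_denominator(best_j + eps)
  (best_j - x_r2_j) / den
}

#' Evolutionary sense probability
#'
#' A stochastic scalar in \[-2, 2\] modulating belly walking. The printed form
#' is `2 * r3 * (1 - 1/T)` (constant in t); because the quantity is described
#' as decreasing over the run, the default variant substitutes `t/T` for
#' `1/T`, which decays to 0 at the final iteration.
#'
#' @param t current iteration (1..T).
#' @param T_max iteration budget.
#' @param r3 a draw in \[-1, 1\].
#' @param variant `"decaying"` or `"as_printed"`.
#' @return a value in \[-2, 2\].
#' @export
#' @examples
#' rsa_evolutionary_sense(1, 100, 1, "as_printed")  # 1.98
rsa_evolutionary_sense <- function(t, T_max, r3,
                                   variant = c("decaying", "as_printed")) {
  switch(match.arg(variant),
         decaying   = 2 * r3 * (1 - t / T_max),
         as_printed = 2 * r3 * (1 - 1 / T_max))
}

#' Chaotic perturbation-scale schedule
#'
#' `sigma_t = ((T - t)/T)^n * (sigma_initial - sigma_final) +
#' sigma_final * z_t`, where `z_t` is the logistic-map iterate at iteration t.
#' The first term decays polynomially from `sigma_initial - sigma_final` to 0;
#' the chaotic second term keeps a small, erratically varying floor so late
#' iterations still probe locally.
#'
#' @param t current iteration.
#' @param T_max iteration budget.
#' @param n decay exponent (default 2).
#' @param sigma_initial,sigma_final schedule endpoints,
#'   `sigma_initial >= sigma_final >= 0`.
#' @param z_t chaotic value in \[0, 1\].
#' @return the scale `sigma_t`.
#' @export
sigma_schedule <- function(t, T_max, n = 2, sigma_initial = 1,
                           sigma_final = 0.01, z_t = 0.5) {
  ((T_max - t) / T_max)^n * (sigma_initial - sigma_final) +
    sigma_final * z_t
}

## evaluate objective; non-finite values become +Inf (search continues)
erso_evaluate <- function(fn, x, env) {
  v <- fn(x)
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || !is.finite(v)) {
    if (!isTRUE(env$nonfinite_warned)) {
      warning("objective returned a non-finite value; candidate assigned +Inf",
              call. = FALSE)
      env$nonfinite_warned <- TRUE
    }
    env$nonfinite <- env$nonfinite + 1L
    v <- Inf
  }
  env$evaluations <- env$evaluations + 1L
  v
}

#' Chaotic-enhanced Reptile Search optimization
#'
#' Minimizes a scalar objective over a box by the Reptile Search Algorithm: a
#' population of candidates moves through four behavioural phases over the
#' iteration budget — high walking and belly walking (exploration,
#' "encircling") in the first half, hunting coordination and hunting
#' cooperation (exploitation) in the second — always relative to the best
#' solution found so far. The chaotic enhancements are (i) logistic-map
#' initialization combined with opposition-based learning (each chaotic
#' candidate and its bound-reflected opposite are evaluated and the better
#' half kept), (ii) an opposition refresh of the worst candidate with
#' probability `p_opp` per iteration, and (iii) an optional greedy Gaussian
#' perturbation whose scale follows the decaying chaotic schedule
#' [sigma_schedule()].
#'
#' @section Phase updates:
#' With `best_j` the best-so-far coordinate, `eta`, `P`, `R`, `ES` as in
#' [rsa_hunting_eta()], [rsa_percent_diff()], [rsa_reduce_factor()] and
#' [rsa_evolutionary_sense()], and `rnd` uniform on \[0, 1\], the new
#' coordinate of candidate i is
#' \describe{
#'   \item{t <= T/4 (high walking)}{`best_j - eta * beta - R * rnd`}
#'   \item{T/4 < t <= T/2 (belly walking)}{`best_j * x_r1_j * ES * rnd`}
#'   \item{T/2 < t <= 3T/4 (hunting coordination)}{`best_j * P * rnd`}
#'   \item{3T/4 < t <= T (hunting cooperation)}{`best_j - eta * e' - R * rnd`}
#' }
#' followed by a hard clip to the bounds.
#'
#' @section Random draw order:
#' All randomness comes from R's RNG seeded once with `seed`. The order is
#' fixed so runs are reproducible and small instances can be transcribed by
#' hand: initialization first (chaotic seed draw, then either `N * d` uniform
#' deviates or the chaotic stream); then per iteration and per candidate `i`:
#' `r1` (`sample.int(N, 1)`), `r2` (`sample.int(N, 1)`), `r3`
#' (`runif(1, -1, 1)`), a vector of `d` `rnd` deviates, and — in uniform
#' epsilon mode only — vectors of `d` deviates on \[0, 2\] for each stabiliser
#' the phase uses, in the order `e'_P` (phases 1, 3, 4), `e'_R` (phases 1, 4),
#' `e'_e` (phase 4). The opposition refresh draws one deviate per iteration
#' only when `p_opp > 0`; the perturbation step draws one deviate per
#' candidate (plus `d` normal deviates when triggered) only when
#' `perturb_prob > 0`.
#'
#' @param fn objective: a function of a length-`d` numeric vector returning a
#'   finite scalar to minimize. Non-finite returns are treated as `+Inf`.
#' @param lower,upper numeric vectors of box bounds (`lower < upper`).
#' @param control an [erso_control()] list.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return an object of class `"erso"`: a list with `par` (best position),
#'   `value` (best fitness), `history` (best fitness after initialization and
#'   each iteration, length `T_max + 1`, non-increasing), `evaluations_history`
#'   (cumulative objective evaluations at the same points), `evaluations`,
#'   `nonfinite` (count of non-finite objective returns), `control` and
#'   `seed`.
#' @seealso [benchmark_function()] for test objectives,
#'   [convergence_history()] to export the trace.
#' @export
#' @examples
#' res <- erso(function(x) sum(x^2), lower = c(-5, -5), upper = c(5, 5),
#'             control = erso_control(N = 10, T_max = 50), seed = 1)
#' res$value < 1
erso <- function(fn, lower, upper, control = erso_control(), seed = NULL) {
  stopifnot(inherits(control, "erso_control"))
  d <- length(lower)
  if (d < 1 || length(upper) != d) fail("invalid bounds")
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    fail("need finite `lower < upper` in every dimension")
  if (!is.null(seed)) set.seed(as.integer(seed))

  N <- control$N; T_max <- control$T_max
  env <- new.env(parent = emptyenv())
  env$evaluations <- 0L; env$nonfinite <- 0L
  chaos <- chaotic_sequence(a = control$chaos_a)

  ## --- initialization ---------------------------------------------------
  range_ <- upper - lower
  if (control$init == "chaotic_opposition") {
    z <- chaos(N * d)
    X0 <- matrix(lower, N, d, byrow = TRUE) +
      matrix(z, N, d) * matrix(range_, N, d, byrow = TRUE)
    Xopp <- matrix(lower + upper, N, d, byrow = TRUE) - X0
    cand <- rbind(X0, Xopp)
    fit <- apply(cand, 1, function(x) erso_evaluate(fn, x, env))
    keep <- order(fit)[seq_len(N)]
    X <- cand[keep, , drop = FALSE]
    fitness <- fit[keep]
  } else {
    X <- matrix(lower, N, d, byrow = TRUE) +
      matrix(stats::runif(N * d), N, d) * matrix(range_, N, d, byrow = TRUE)
    fitness <- apply(X, 1, function(x) erso_evaluate(fn, x, env))
  }
  best_i <- which.min(fitness)
  best_x <- X[best_i, ]
  best_f <- fitness[best_i]

  history <- numeric(T_max + 1L)
  eval_hist <- integer(T_max + 1L)
  history[1L] <- best_f
  eval_hist[1L] <- env$evaluations

  eps_draw <- function(n) {
    if (control$epsilon_mode == "uniform") stats::runif(n, 0, 2)
    else rep(control$epsilon_fixed, n)
  }

  ## --- main loop --------------------------------------------------------
  for (t in seq_len(T_max)) {
    z_t <- chaos(1)
    X_old <- X
    phase <- if (t <= T_max / 4) 1L
             else if (t <= 2 * T_max / 4) 2L
             else if (t <= 3 * T_max / 4) 3L
             else 4L

    for (i in seq_len(N)) {
      r1 <- sample.int(N, 1L)
      r2 <- sample.int(N, 1L)
      r3 <- stats::runif(1, -1, 1)
      rnd <- stats::runif(d)
      avg_i <- mean(X_old[i, ])

      ## inlined forms of rsa_percent_diff / rsa_hunting_eta /
      ## rsa_reduce_factor so the denominator guard warns once per run
      P_of <- function(eps)
        control$alpha + (X_old[i, ] - avg_i) /
          guard_denominator(best_x * (upper - lower) + eps, env = env)
      R_of <- function(eps)
        (best_x - X_old[r2, ]) / guard_denominator(best_x + eps, env = env)
      if (phase == 1L) {
        eP <- eps_draw(d)
        eR <- eps_draw(d)
        eta <- best_x * P_of(eP)
        R <- R_of(eR)
        x_new <- best_x - eta * control$beta - R * rnd
      } else if (phase == 2L) {
        ES <- rsa_evolutionary_sense(t, T_max, r3, control$es_variant)
        x_new <- best_x * X_old[r1, ] * ES * rnd
      } else if (phase == 3L) {
        eP <- eps_draw(d)
        x_new <- best_x * P_of(eP) * rnd
      } else {
        eP <- eps_draw(d)
        eR <- eps_draw(d)
        eE <- eps_draw(d)
        eta <- best_x * P_of(eP)
        R <- R_of(eR)
        x_new <- best_x - eta * eE - R * rnd
      }

      x_new <- clip_to_bounds(x_new, lower, upper)
      f_new <- erso_evaluate(fn, x_new, env)
      X[i, ] <- x_new
      fitness[i] <- f_new
      if (f_new < best_f) { best_f <- f_new; best_x <- x_new }
    }

    ## opposition refresh of the worst candidate
    if (control$p_opp > 0 && stats::runif(1) < control$p_opp) {
      w <- which.max(fitness)
      x_opp <- clip_to_bounds(opposite_point(X[w, ], lower, upper),
                              lower, upper)
      f_opp <- erso_evaluate(fn, x_opp, env)
      if (f_opp < fitness[w]) { X[w, ] <- x_opp; fitness[w] <- f_opp }
      if (f_opp < best_f) { best_f <- f_opp; best_x <- x_opp }
    }

    ## greedy chaotic perturbation
    if (control$perturb_prob > 0) {
      sigma_t <- sigma_schedule(t, T_max, control$sigma_exponent,
                                control$sigma_initial, control$sigma_final,
                                z_t)
      for (i in seq_len(N)) {
        if (stats::runif(1) < control$perturb_prob) {
          x_try <- clip_to_bounds(
            X[i, ] + stats::rnorm(d) * sigma_t * range_, lower, upper)
          f_try <- erso_evaluate(fn, x_try, env)
          if (f_try < fitness[i]) { X[i, ] <- x_try; fitness[i] <- f_try }
          if (f_try < best_f) { best_f <- f_try; best_x <- x_try }
        }
      }
    }

    history[t + 1L] <- best_f
    eval_hist[t + 1L] <- env$evaluations
  }

  structure(list(par = best_x, value = best_f, history = history,
                 evaluations_history = eval_hist,
                 evaluations = env$evaluations, nonfinite = env$nonfinite,
                 population = X, fitness = fitness,
                 control = control, seed = seed),
            class = "erso")
}

#' @export
print.erso <- function(x, ...) {
  cat("Chaotic Reptile Search optimization\n")
  cat(sprintf("  dimensions: %d   population: %d   iterations: %d\n",
              length(x$par), x$control$N, x$control$T_max))
  cat(sprintf("  best value: %.6g after %d evaluations\n",
              x$value, x$evaluations))
  cat("  best position:", format(x$par, digits = 6), "\n")
  invisible(x)
}

#' Plot an optimizer convergence trace
#'
#' Best-so-far fitness against iteration, on a log axis when all values are
#' positive.
#'
#' @param x an `"erso"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.erso <- function(x, ...) {
  logy <- if (all(x$history > 0)) "y" else ""
  graphics::plot(seq_along(x$history) - 1L, x$history, type = "l",
                 log = logy, xlab = "iteration", ylab = "best fitness", ...)
  invisible(x)
}

#' Convergence history as a data frame
#'
#' @param result an `"erso"` object.
#' @param file optional path; when given the table is also written as CSV.
#' @return data frame with columns `iteration` (0 = after initialization),
#'   `best_fitness` and `evaluations` (cumulative).
#' @export
convergence_history <- function(result, file = NULL) {
  stopifnot(inherits(result, "erso"))
  df <- data.frame(iteration = seq_along(result$history) - 1L,
                   best_fitness = result$history,
                   evaluations = result$evaluations_history)
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
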