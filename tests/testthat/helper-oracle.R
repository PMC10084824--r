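## Straight-line transcription of the optimizer's update equations for a
## small instance (N = 2, d = 1, uniform init, fixed epsilon, no opposition
## refresh or perturbation), replaying the same recorded draw stream. Used to
## check the optimizer against an independent implementation of the maths.
erso_transcription_oracle <- function(seed, T_max = 4L, lo = -4, hi = 6,
                                      fn = function(x) x^2) {
  N <- 2L
  set.seed(seed)
  forbidden <- c(0, 0.25, 0.5, 0.75)
  repeat {                       # the chaotic stream seed draw
    x0 <- runif(1)
    if (min(abs(x0 - forbidden)) > 1e-9) break
  }
  X <- lo + runif(N) * (hi - lo)
  fit <- vapply(X, fn, numeric(1))
  best_x <- X[which.min(fit)]
  best_f <- min(fit)
  alpha <- 0.1; beta <- 0.1; eps <- 1e-10
  guard <- function(den) {       # documented 1e-10 magnitude floor
    if (abs(den) < 1e-10) {
      s <- sign(den); if (s == 0) s <- 1
      s * 1e-10
    } else den
  }
  for (t in seq_len(T_max)) {
    X_old <- X                   # neighbours read from the iteration snapshot
    for (i in 1:N) {
      r1 <- sample.int(N, 1); r2 <- sample.int(N, 1)
      r3 <- runif(1, -1, 1); rnd <- runif(1)
      avg <- X_old[i]
      P <- alpha + (X_old[i] - avg) / guard(best_x * (hi - lo) + eps)
      eta <- best_x * P
      R <- (best_x - X_old[r2]) / guard(best_x + eps)
      x_new <- if (t <= T_max / 4) {
        best_x - eta * beta - R * rnd
      } else if (t <= 2 * T_max / 4) {
        best_x * X_old[r1] * (2 * r3 * (1 - t / T_max)) * rnd
      } else if (t <= 3 * T_max / 4) {
        best_x * P * rnd
      } else {
        best_x - eta * eps - R * rnd
      }
      x_new <- min(max(x_new, lo), hi)
      f_new <- fn(x_new)
      X[i] <- x_new; fit[i] <- f_new
      if (f_new < best_f) { best_f <- f_new; best_x <- x_new }
    }
  }
  list(par = best_x, value = best_f, X = X)
}

## run the packaged optimizer under the matching settings
erso_small_instance <- function(seed, T_max = 4L, lo = -4, hi = 6,
                                fn = function(x) x^2) {
  erso(fn, lo, hi,
       erso_control(N = 2, T_max = T_max, init = "uniform",
                    epsilon_mode = "fixed", epsilon_fixed = 1e-10,
                    p_opp = 0, perturb_prob = 0, es_variant = "decaying"),
       seed = seed)
}
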