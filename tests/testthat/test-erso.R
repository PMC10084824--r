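test_that("benchmark functions match their closed forms at known points", {
  expect_equal(benchmark_function("sphere", c(0, 0, 0)), 0)
  expect_equal(benchmark_function("sphere", c(1, 1)), 2)
  expect_equal(benchmark_function("rastrigin", rep(0, 5)), 0)
  expect_equal(benchmark_function("rosenbrock", c(1, 1, 1)), 0)
  expect_equal(benchmark_function("ackley", c(0, 0)), 0, tolerance = 1e-12)
  expect_equal(benchmark_function("griewank", c(0, 0, 0)), 0)
  expect_error(benchmark_function("nope", 0), "arg")
  expect_error(benchmark_function("sphere", c(1, NA)), "finite")
})

test_that("update-rule ingredients evaluate to their worked values", {
  ## percentage difference
  expect_equal(rsa_percent_diff(2, 2, 5, 0, 10, alpha = 0.1, eps = 0.3), 0.1)
  expect_equal(rsa_percent_diff(1, 2, 2, 0, 10, alpha = 0.1, eps = 0.5),
               0.1 - 1 / 20.5)
  expect_equal(rsa_percent_diff(3, 3, 1, 0, 1, alpha = 0, eps = 0.2), 0)
  ## hunting operator
  expect_equal(rsa_hunting_eta(2, 0.1), 0.2)
  expect_equal(rsa_hunting_eta(0, 123), 0)
  expect_equal(rsa_hunting_eta(-1, 0.5), -0.5)
  ## reduce factor
  expect_equal(rsa_reduce_factor(1, 1, 0.5), 0)
  expect_equal(rsa_reduce_factor(1, 0, 1), 0.5)
  expect_equal(rsa_reduce_factor(0, 1, 2), -0.5)
  expect_warning(rsa_reduce_factor(0, 1, 0), "floor")
  ## evolutionary sense
  expect_equal(rsa_evolutionary_sense(3, 10, 0, "decaying"), 0)
  expect_equal(rsa_evolutionary_sense(10, 10, 0.7, "decaying"), 0)
  expect_equal(rsa_evolutionary_sense(1, 100, 1, "as_printed"), 1.98)
})

test_that("evolutionary sense stays within [-2, 2] for both variants", {
  for (variant in c("decaying", "as_printed"))
    for (T_max in c(4, 10, 100))
      for (t in seq_len(T_max))
        for (r3 in c(-1, -0.5, 0, 0.5, 1)) {
          es <- rsa_evolutionary_sense(t, T_max, r3, variant)
          expect_gte(es, -2); expect_lte(es, 2)
        }
})

test_that("perturbation-scale schedule interpolates and decays", {
  expect_equal(sigma_schedule(10, 10, 2, 1, 0.01, z_t = 0.7), 0.01 * 0.7)
  expect_equal(sigma_schedule(0, 10, 1, 1, 0.01, z_t = 0.5), 0.99 + 0.005)
  expect_equal(sigma_schedule(3, 7, 3, 0.4, 0.4, z_t = 1), 0.4)
})

test_that("initial populations respect bounds; opposition init is never worse", {
  sphere <- function(x) sum(x^2)
  lo <- c(-5, -5, -5); hi <- c(5, 5, 5)
  for (mode in c("uniform", "chaotic_opposition")) {
    res <- erso(sphere, lo, hi,
                erso_control(N = 10, T_max = 4, init = mode,
                             perturb_prob = 0, p_opp = 0), seed = 3)
    expect_true(all(res$population >= matrix(lo, 10, 3, byrow = TRUE) &
                    res$population <= matrix(hi, 10, 3, byrow = TRUE)))
  }
  ## chaotic+opposition keeps the better of each pair: the kept set must be
  ## at least as good as the plain chaotic half evaluated alone
  set.seed(11)
  ch <- chaotic_sequence()
  z <- ch(10 * 3)
  X0 <- matrix(lo, 10, 3, byrow = TRUE) + matrix(z, 10, 3) *
    matrix(hi - lo, 10, 3, byrow = TRUE)
  Xopp <- matrix(lo + hi, 10, 3, byrow = TRUE) - X0
  f_plain <- apply(X0, 1, sphere)
  f_all <- c(f_plain, apply(Xopp, 1, sphere))
  expect_lte(min(sort(f_all)[1:10]), min(f_plain))
})

test_that("optimize honours its contracts on simple objectives", {
  ctrl <- erso_control(N = 8, T_max = 12)
  r <- erso(function(x) 7, c(0), c(1), ctrl, seed = 5)
  expect_equal(r$value, 7)
  expect_length(r$history, 13)
  ## determinism: same seed, bit-identical result
  f <- function(x) sum((x - 1)^2)
  a <- erso(f, c(-4, -4), c(4, 4), ctrl, seed = 42)
  b <- erso(f, c(-4, -4), c(4, 4), ctrl, seed = 42)
  expect_identical(a[setdiff(names(a), "control")],
                   b[setdiff(names(b), "control")])
  ## non-finite objective values are survivable
  g <- function(x) if (x[1] > 0) NaN else sum(x^2)
  expect_warning(r2 <- erso(g, c(-2), c(2), ctrl, seed = 1), "non-finite")
  expect_true(is.finite(r2$value))
  expect_gt(r2$nonfinite, 0)
})

test_that("best-so-far is monotone and iterates stay in bounds", {
  set.seed(99)
  for (k in 1:5) {
    A <- matrix(rnorm(4), 2)
    f <- function(x) sum((A %*% x)^2) + sin(3 * x[1])
    res <- erso(f, c(-3, -2), c(2, 4),
                erso_control(N = 6, T_max = 20), seed = k)
    expect_true(all(diff(res$history) <= 0))
    expect_true(all(res$population >= matrix(c(-3, -2), 6, 2, byrow = TRUE) -
                      1e-12))
    expect_true(all(res$population <= matrix(c(2, 4), 6, 2, byrow = TRUE) +
                      1e-12))
  }
})

test_that("optimizer trace matches a straight-line transcription (N=2, d=1, T=4)", {
  for (seed in c(77, 3)) {
    res <- erso_small_instance(seed)
    want <- erso_transcription_oracle(seed)
    expect_identical(res$par, want$par)
    expect_identical(res$value, want$value)
    expect_identical(unname(res$population[, 1]), unname(want$X))
  }
})

test_that("convergence history exports iteration, fitness and evaluations", {
  r <- erso(function(x) sum(x^2), c(-1, -1), c(1, 1),
            erso_control(N = 4, T_max = 6), seed = 2)
  h <- convergence_history(r)
  expect_equal(names(h), c("iteration", "best_fitness", "evaluations"))
  expect_equal(nrow(h), 7)
  expect_equal(h$iteration, 0:6)
  expect_true(all(diff(h$evaluations) >= 0))
  f <- tempfile(fileext = ".csv")
  convergence_history(r, f)
  expect_equal(read.csv(f), h)
})
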