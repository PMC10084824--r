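test_that("logistic map evaluates the recurrence and rejects bad inputs", {
  expect_equal(logistic_map_step(0.3, 4), 0.84)
  expect_equal(logistic_map_step(0.5, 4), 1.0)
  expect_equal(logistic_map_step(0.84, 4), 0.5376)
  expect_error(logistic_map_step(1.2, 4), "\\[0, 1\\]")
  expect_error(logistic_map_step(0.3, 4.5), "\\(0, 4\\]")
  expect_error(logistic_map_step(0.3, 0), "\\(0, 4\\]")
})

test_that("chaotic iterates stay in [0,1] and are ergodic with mean 1/2", {
  x <- 0.3
  xs <- numeric(10000)
  for (k in seq_along(xs)) {
    x <- logistic_map_step(x, 4)
    xs[k] <- x
  }
  expect_true(all(xs >= 0 & xs <= 1))
  expect_lt(abs(mean(xs) - 0.5), 0.05)
})

test_that("chaotic_sequence refuses degenerate seeds and streams iterates", {
  expect_error(chaotic_sequence(0.25), "avoid")
  expect_error(chaotic_sequence(0.75), "avoid")
  s <- chaotic_sequence(0.3)
  expect_equal(s(2), c(0.84, 0.5376))
  set.seed(1)
  s2 <- chaotic_sequence()     # seed drawn from the RNG
  v <- s2(100)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("opposition is the bound reflection and an exact involution", {
  expect_equal(opposite_point(2, 0, 10), 8)
  expect_equal(opposite_point(5, 0, 10), 5)            # midpoint fixed
  expect_equal(opposite_point(c(0, 1), c(0, 1), c(10, 3)), c(10, 3))
  expect_error(opposite_point(c(1, 2), 0, 10), "length")
  set.seed(42)
  for (k in 1:20) {
    ## exact involution on a symmetric box; 1-ulp agreement on general boxes
    hi_s <- runif(4, 0.5, 3)
    xs <- runif(4, -1, 1) * hi_s
    expect_identical(opposite_point(opposite_point(xs, -hi_s, hi_s),
                                    -hi_s, hi_s), xs)
    lo <- rnorm(4); hi <- lo + runif(4, 0.5, 3)
    x <- lo + runif(4) * (hi - lo)
    expect_equal(opposite_point(opposite_point(x, lo, hi), lo, hi), x,
                 tolerance = 1e-12)
  }
})
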