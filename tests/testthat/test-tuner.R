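test_that("unit-hypercube decoding follows the stated rules", {
  sp <- hyperparam_space()
  lo <- decode_hyperparams(rep(0, nrow(sp)), sp)
  hi <- decode_hyperparams(rep(1, nrow(sp)), sp)
  for (k in seq_len(nrow(sp))) {
    expect_equal(lo[[sp$name[k]]], sp$lower[k], tolerance = 1e-12)
    expect_equal(hi[[sp$name[k]]], sp$upper[k], tolerance = 1e-12)
  }
  ## integer rule: lb + floor(u * (ub - lb + 1)), clipped
  sp2 <- hyperparam_space(data.frame(name = "m", kind = "integer",
                                     lower = 1, upper = 8))
  expect_identical(decode_hyperparams(0.5, sp2)$m, 5L)
  expect_identical(decode_hyperparams(0.999, sp2)$m, 8L)
  ## monotone per dimension
  us <- seq(0, 1, by = 0.05)
  for (k in seq_len(nrow(sp))) {
    vals <- vapply(us, function(u) {
      v <- rep(0.5, nrow(sp)); v[k] <- u
      as.numeric(decode_hyperparams(v, sp)[[sp$name[k]]])
    }, numeric(1))
    expect_true(all(diff(vals) >= 0))
  }
  expect_error(decode_hyperparams(rep(1.2, nrow(sp)), sp), "\\[0, 1\\]")
  expect_error(decode_hyperparams(0.5, sp), "length")
})

test_that("search-space validation rejects malformed spaces", {
  expect_error(hyperparam_space(data.frame(name = "a", kind = "weird",
                                           lower = 0, upper = 1)), "kinds")
  expect_error(hyperparam_space(data.frame(name = "a", kind = "log",
                                           lower = 0, upper = 1)), "positive")
  expect_error(hyperparam_space(data.frame(name = "a", kind = "continuous",
                                           lower = 2, upper = 1)), "lower")
})

test_that("fitness is a cached deterministic error rate in [0, 1]", {
  sep <- separable_xy(150, p = 10)
  st <- list(learning_rate = 0.05, filters1 = 6, filters2 = 8, kernel = 3,
             pool = 2, latent = 3, finetune_epochs = 120, batch_size = 32)
  cache <- new.env()
  f1 <- evaluate_fitness(st, sep$x, sep$y, seed = 2, cache = cache,
                         pretrain_epochs = 2)
  f2 <- evaluate_fitness(st, sep$x, sep$y, seed = 2, cache = cache,
                         pretrain_epochs = 2)
  expect_identical(f1, f2)
  expect_gte(f1, 0); expect_lte(f1, 1)
  ## wide-margin separable data with an adequate setting scores well
  expect_lte(f1, 0.05)
  ## infeasible decoded architectures get the soft penalty, not an error
  bad <- st; bad$kernel <- 40
  expect_warning(fb <- evaluate_fitness(bad, sep$x, sep$y, seed = 2),
                 "infeasible")
  expect_identical(fb, 1)
})

test_that("tuning improves on the initial population and accounts its budget", {
  set.seed(10)
  d <- generate_soil_data(small_design(15), seed = 30)
  x <- as.matrix(d[, soil_features])
  y <- d$B_F
  ctrl <- erso_control(N = 4, T_max = 4, perturb_prob = 0.1)
  tr <- tune_cae(x, y, control = ctrl, seed = 21, pretrain_epochs = 2)
  expect_s3_class(tr, "cae_tune")
  ## optimizer monotonicity: final best cannot exceed the initial best
  expect_lte(tr$best_fitness, tr$optimizer$history[1])
  ## budget accounting: distinct trainings never exceed objective calls,
  ## which are bounded by N * (T + 1) plus logged extra evaluations
  expect_lte(tr$n_trainings, tr$optimizer$evaluations)
  ## init (2N with opposition) + N per iteration + opposition refresh (<= 1
  ## per iteration) + perturbations (<= N per iteration)
  expect_lte(tr$optimizer$evaluations,
             2 * ctrl$N + ctrl$N * ctrl$T_max + ctrl$T_max +
               ctrl$N * ctrl$T_max)
  expect_equal(nrow(tr$log), tr$n_trainings)
  expect_true(all(tr$log$fitness >= 0 & tr$log$fitness <= 1))
  expect_equal(min(tr$log$fitness), tr$best_fitness)
  ## the returned model is trained with the best decoded setting
  expect_s3_class(tr$model, "cae")
  expect_output(print(tr), "best validation error")
  f <- tempfile(fileext = ".csv")
  write_tuning_log(tr, f)
  expect_equal(nrow(read.csv(f)), tr$n_trainings)
})
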