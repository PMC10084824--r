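test_that("layer primitives reproduce hand-computed values", {
  ## convolution
  expect_equal(conv1d_forward(c(1, 2, 3), 1), c(1, 2, 3))
  expect_equal(conv1d_forward(c(1, 2, 3), c(1, 1), bias = 1), c(4, 6))
  expect_equal(conv1d_forward(c(1, 2, 3), c(1, 1), bias = 1,
                              activation = "tanh"),
               tanh(c(4, 6)))
  expect_error(conv1d_forward(c(1, 2), c(1, 1, 1, 1)), "longer")
  ## downsampling
  expect_equal(downsample(c(2, 4), 2), 3)
  expect_equal(downsample(c(1, 2, 3, 4), 2, beta = 2, bias = 1), c(4, 8))
  expect_equal(downsample(c(5, 9), 2, beta = 0, bias = 0.3,
                          activation = "tanh"),
               tanh(0.3))
  expect_error(downsample(1:4, 0), "positive")
  ## classification head
  expect_equal(classify_head(c(1, 1), matrix(0, 2, 3), rep(0, 3)),
               rep(1 / 3, 3))
  expect_equal(classify_head(1, matrix(0, 1, 2), c(0, log(3))),
               c(0.25, 0.75))
  p <- classify_head(rnorm(4), matrix(rnorm(8), 4, 2), rnorm(2))
  expect_equal(sum(p), 1)
  expect_true(all(p > 0 & p < 1))
  expect_error(classify_head(c(1, 1, 1), matrix(0, 2, 3), rep(0, 3)),
               "conform")
  ## reconstruction loss
  expect_equal(reconstruction_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(reconstruction_loss(c(0, 0), c(1, 1)), 1)
  expect_equal(reconstruction_loss(c(1, 2), c(0, 0)), 2.5)
  expect_error(reconstruction_loss(1:3, 1:2), "match")
})

test_that("architecture validation enforces the compression contract", {
  a <- cae_architecture(10, classes = 3)
  expect_s3_class(a, "cae_architecture")
  expect_lt(a$latent, a$input_len)
  expect_error(cae_architecture(10, latent = 10, classes = 2), "compression")
  expect_error(cae_architecture(10, latent = 12, classes = 2), "compression")
  expect_error(cae_architecture(10, classes = 1), "classes")
  expect_error(
    cae_architecture(4, blocks = list(list(filters = 2, kernel = 6, pool = 1)),
                     latent = 2, classes = 2),
    "kernel")
  ## every admissible architecture compresses: encoder output < input length
  for (latent in 2:6)
    expect_lt(cae_architecture(8, latent = latent, classes = 2)$latent, 8)
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  arch <- tiny_arch()
  params <- soilcae:::cae_init_params(arch)
  X <- matrix(rnorm(4 * 6), 4)
  Y1h <- soilcae:::one_hot(c(1L, 2L, 1L, 2L), 2L)
  gap_ae <- fd_gradient_gap(function(p) soilcae:::cae_ae_grad(p, arch, X),
                            params)
  gap_clf <- fd_gradient_gap(function(p)
    soilcae:::cae_clf_grad(p, arch, X, Y1h, TRUE), params)
  expect_lt(gap_ae, 1e-4)
  expect_lt(gap_clf, 1e-4)
})

test_that("fused compiled training paths match the per-layer reference path", {
  set.seed(1)
  arch <- cae_architecture(10, latent = 4, classes = 3)
  params <- soilcae:::cae_init_params(arch)
  X <- matrix(rnorm(30 * 10), 30)
  Y1h <- soilcae:::one_hot(sample(1:3, 30, TRUE), 3L)
  a <- soilcae:::cae_clf_grad(params, arch, X, Y1h, TRUE)
  b <- soilcae:::cae_clf_grad_fused(params, arch, X, Y1h, TRUE,
                                    soilcae:::zero_like(params),
                                    soilcae:::arch_blockinfo(arch))
  expect_equal(a$loss, b$loss, tolerance = 1e-12)
  expect_equal(soilcae:::pack_params(a$grad), soilcae:::pack_params(b$grad),
               tolerance = 1e-12)
  H <- array(X, c(30, 10, 1))
  a2 <- soilcae:::block_ae_grad(params, arch, 1, H)
  b2 <- soilcae:::block_ae_grad_fused(params, arch, 1, H)
  expect_equal(a2$loss, b2$loss, tolerance = 1e-12)
  expect_equal(soilcae:::pack_params(a2$grad), soilcae:::pack_params(b2$grad),
               tolerance = 1e-12)
})

test_that("zero-epoch phases leave the initialized weights untouched", {
  sep <- separable_xy(40)
  ctrl0 <- cae_control(pretrain_epochs = 0, finetune_epochs = 0)
  fit <- cae(sep$x, sep$y, control = ctrl0, seed = 8)
  set.seed(8L)
  init <- soilcae:::cae_init_params(fit$arch)
  expect_identical(soilcae:::pack_params(fit$params),
                   soilcae:::pack_params(init))
  expect_equal(nrow(fit$history), 0)
})

test_that("training is deterministic in the seed", {
  sep <- separable_xy(60)
  ctrl <- cae_control(pretrain_epochs = 2, finetune_epochs = 10)
  f1 <- cae(sep$x, sep$y, control = ctrl, seed = 5)
  f2 <- cae(sep$x, sep$y, control = ctrl, seed = 5)
  expect_identical(soilcae:::pack_params(f1$params),
                   soilcae:::pack_params(f2$params))
  expect_identical(f1$history, f2$history)
  f3 <- cae(sep$x, sep$y, control = ctrl, seed = 6)
  expect_false(identical(soilcae:::pack_params(f1$params),
                         soilcae:::pack_params(f3$params)))
})

test_that("pretraining drives reconstruction loss down on constant data", {
  ## identical constant rows are trivially reconstructable; every stage's
  ## loss must collapse and the smoothed curve must be non-increasing
  arch <- tiny_arch()
  X <- matrix(2.5, 80, 6)
  ctrl <- cae_control(pretrain_epochs = 50, finetune_epochs = 0,
                      learning_rate = 0.05)
  set.seed(4)
  params <- soilcae:::cae_init_params(arch)
  res <- soilcae:::pretrain_autoencoder(params, arch, X, ctrl)
  h <- res$history
  expect_equal(nrow(h), 50 * 3)   # two blocks + latent stage
  for (st in unique(h$stage)) {
    l <- h[h$stage == st, "loss"]
    expect_lt(l[length(l)], 0.1 * l[1])
    sm <- stats::filter(l, rep(1 / 5, 5), sides = 1)
    sm <- sm[!is.na(sm)]
    expect_true(all(diff(sm) <= 1e-6))
  }
})

test_that("fine-tuning separates a wide-margin two-class problem", {
  sep <- separable_xy(240)
  fit <- cae(sep$x, sep$y,
             control = cae_control(pretrain_epochs = 5, finetune_epochs = 100),
             seed = 2)
  expect_gte(fit$training_accuracy, 0.95)
  expect_equal(nrow(fit$history[fit$history$phase == "finetune", ]), 100)
})

test_that("degenerate single-class training predicts that class", {
  x <- matrix(rnorm(30 * 6), 30)
  y <- factor(rep("only", 30))
  fit <- cae(x, y, control = cae_control(pretrain_epochs = 0,
                                         finetune_epochs = 40), seed = 1)
  expect_true(all(predict(fit, x) == "only"))
})

test_that("predictions are probabilistic, consistent and stateless", {
  sep <- separable_xy(80)
  fit <- cae(sep$x, sep$y,
             control = cae_control(pretrain_epochs = 2, finetune_epochs = 20),
             seed = 3)
  p <- predict(fit, sep$x, type = "prob")
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
  lab <- predict(fit, sep$x)
  expect_equal(as.character(lab),
               colnames(p)[max.col(p, ties.method = "first")])
  perm <- sample(nrow(sep$x))
  expect_identical(predict(fit, sep$x[perm, ]), lab[perm])
  expect_error(predict(fit, sep$x[, 1:3]), "features")
  z <- predict(fit, sep$x, type = "latent")
  expect_equal(dim(z), c(80, fit$arch$latent))
})

test_that("encoder/decoder round trip is exact at zero under identity activation", {
  arch <- cae_architecture(8, latent = 3, classes = 2,
                           activation = "identity")
  set.seed(1)
  params <- soilcae:::cae_init_params(arch)   # biases start at zero
  X0 <- matrix(0, 3, 8)
  enc <- soilcae:::encoder_forward(X0, arch, params)
  dec <- soilcae:::decoder_forward(enc$z, arch, params)
  expect_equal(enc$z, matrix(0, 3, arch$latent))
  expect_equal(dec$xhat, X0)
})

test_that("checkpoints round-trip weights and predictions exactly", {
  sep <- separable_xy(50)
  fit <- cae(sep$x, sep$y,
             control = cae_control(pretrain_epochs = 2, finetune_epochs = 10),
             seed = 7)
  f <- tempfile(fileext = ".json")
  write_cae(fit, f)
  back <- read_cae(f)
  expect_identical(soilcae:::pack_params(back$params),
                   soilcae:::pack_params(fit$params))
  expect_identical(back$levels, fit$levels)
  expect_identical(unname(back$center), unname(fit$center))
  expect_identical(predict(back, sep$x, type = "prob"),
                   predict(fit, sep$x, type = "prob"))
})

test_that("training curves export and summary/print run", {
  sep <- separable_xy(40)
  fit <- cae(sep$x, sep$y,
             control = cae_control(pretrain_epochs = 2, finetune_epochs = 5),
             seed = 1)
  f <- tempfile(fileext = ".csv")
  h <- write_training_curves(fit, f)
  expect_equal(read.csv(f)$loss, h$loss)
  expect_output(print(fit), "autoencoder-classifier")
  expect_output(print(summary(fit)), "parameters")
  expect_named(coef(fit), c("conv", "pool", "enc", "dec", "deconv", "head"))
})
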