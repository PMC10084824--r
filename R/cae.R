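#' Architecture of the 1-D convolutional autoencoder-classifier
#'
#' Describes the encoder (convolution blocks, each a Tanh convolution followed
#' by a scaled mean-pool, then a dense compression to the latent code), the
#' mirrored decoder (dense expansion, then per block nearest-neighbour
#' upsampling and convolution; the final reconstruction layer is linear), and
#' the softmax classification head on the latent code. The default shape is
#' sized for short soil-test feature vectors (8–12 measurements).
#'
#' @param input_len number of input features.
#' @param blocks list of convolution blocks, each a list with `filters`,
#'   `kernel` and `pool`.
#' @param latent latent code dimension; must be smaller than `input_len`
#'   (the compression contract — the encoder output is the bottleneck, and
#'   the achievable compression is set entirely by this architecture).
#' @param classes number of output classes (at least 2).
#' @param activation `"tanh"` (default) or `"identity"` (analytic checks).
#' @param padding `"same"` (default; keeps short vectors alive through
#'   several blocks) or `"valid"`. The decoder mirror is defined for `"same"`
#'   padding only.
#' @return an object of class `"cae_architecture"` with per-block length
#'   bookkeeping (`len_in`, `len_pool`, padded lengths) and the flattened
#'   feature size.
#' @export
cae_architecture <- function(input_len,
                             blocks = list(list(filters = 8, kernel = 3, pool = 2),
                                           list(filters = 16, kernel = 3, pool = 2)),
                             latent = 4, classes = 2,
                             activation = c("tanh", "identity"),
                             padding = c("same", "valid")) {
  activation <- match.arg(activation)
  padding <- match.arg(padding)
  input_len <- as.integer(input_len)
  if (input_len < 2L) fail("`input_len` must be at least 2")
  if (classes < 2L) fail("`classes` must be at least 2")
  if (latent >= input_len)
    fail("`latent` must be smaller than `input_len` (compression contract)")
  if (!length(blocks)) fail("need at least one convolution block")
  L <- input_len
  C <- 1L
  info <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    s <- as.integer(blk$kernel); p <- as.integer(blk$pool)
    f <- as.integer(blk$filters)
    if (s < 1L || p < 1L || f < 1L) fail("block ", b, ": invalid sizes")
    L_conv <- if (padding == "same") L else L - s + 1L
    if (s > L || L_conv < 1L)
      fail("block ", b, ": kernel size ", s,
           " exceeds feature-map length ", L)
    r <- (p - L_conv %% p) %% p
    L_pool <- (L_conv + r) %/% p
    info[[b]] <- list(filters = f, kernel = s, pool = p, C_in = C,
                      len_in = L, len_conv = L_conv, pad = r,
                      len_pool = L_pool)
    L <- L_pool; C <- f
  }
  flat <- L * C
  if (flat < 1L) fail("architecture collapses the signal to nothing")
  structure(list(input_len = input_len, blocks = info,
                 latent = as.integer(latent), classes = as.integer(classes),
                 activation = activation, padding = padding, flat = flat),
            class = "cae_architecture")
}

#' @export
print.cae_architecture <- function(x, ...) {
  cat(sprintf("1-D CAE architecture: %d features -> latent %d -> %d classes\n",
              x$input_len, x$latent, x$classes))
  for (b in seq_along(x$blocks)) {
    i <- x$blocks[[b]]
    cat(sprintf("  block %d: conv %d filters (kernel %d, %s, %s) -> pool %d: length %d -> %d\n",
                b, i$filters, i$kernel, x$activation, x$padding, i$pool,
                i$len_in, i$len_pool))
  }
  cat(sprintf("  flattened features: %d\n", x$flat))
  invisible(x)
}

#' Training configuration for the CAE
#'
#' @param learning_rate gradient-descent step size (default 0.05, suited to
#'   standardized inputs and Tanh blocks).
#' @param batch_size mini-batch size; values `>= n` give full-batch descent.
#' @param pretrain_epochs unsupervised reconstruction epochs per pre-training
#'   stage (0 disables pre-training).
#' @param finetune_epochs supervised fine-tuning epochs.
#' @param optimizer `"sgd"` (plain gradient descent, the default) or
#'   `"adam"`.
#' @param weight_decay L2 penalty coefficient applied during updates, to the
#'   parameters the current training phase updates.
#' @param pretrain_mode `"layerwise"` (greedy: each block's local autoencoder
#'   is trained and frozen before the next is stacked, then the dense latent
#'   stage) or `"end_to_end"` (whole autoencoder trained jointly).
#' @param encoder_trainable logical; when `FALSE` supervised fine-tuning
#'   updates only the classification head.
#' @return a list of class `"cae_control"`.
#' @export
cae_control <- function(learning_rate = 0.05, batch_size = 32,
                        pretrain_epochs = 10, finetune_epochs = 100,
                        optimizer = c("sgd", "adam"), weight_decay = 0,
                        pretrain_mode = c("layerwise", "end_to_end"),
                        encoder_trainable = TRUE) {
  optimizer <- match.arg(optimizer)
  pretrain_mode <- match.arg(pretrain_mode)
  if (learning_rate <= 0) fail("`learning_rate` must be positive")
  if (pretrain_epochs < 0 || finetune_epochs < 0) fail("epochs must be >= 0")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 optimizer = optimizer, weight_decay = weight_decay,
                 pretrain_mode = pretrain_mode,
                 encoder_trainable = encoder_trainable),
            class = "cae_control")
}

## seeded uniform init scaled by fan-in; pool scales start at 1, biases at 0
cae_init_params <- function(arch) {
  uinit <- function(nr, nc) {
    lim <- 1 / sqrt(nr)
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  B <- length(arch$blocks)
  conv <- pool <- deconv <- vector("list", B)
  for (b in seq_len(B)) {
    i <- arch$blocks[[b]]
    conv[[b]] <- list(W = uinit(i$kernel * i$C_in, i$filters),
                      b = numeric(i$filters))
    pool[[b]] <- list(beta = rep(1, i$filters), bias = numeric(i$filters))
    deconv[[b]] <- list(W = uinit(i$kernel * i$filters, i$C_in),
                        b = numeric(i$C_in))
  }
  list(conv = conv, pool = pool,
       enc = list(W = uinit(arch$flat, arch$latent), b = numeric(arch$latent)),
       dec = list(W = uinit(arch$latent, arch$flat), b = numeric(arch$flat)),
       deconv = deconv,
       head = list(W = uinit(arch$latent, arch$classes),
                   b = numeric(arch$classes)))
}

## ---- full-model forward / backward ----------------------------------------

encoder_forward <- function(X, arch, params) {
  n <- nrow(X)
  x <- array(X, c(n, arch$input_len, 1L))
  B <- length(arch$blocks)
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    i <- arch$blocks[[b]]
    cv <- conv1d_layer_forward(x, params$conv[[b]]$W, params$conv[[b]]$b,
                               arch$activation, arch$padding)
    pl <- pool_layer_forward(cv$y, i$pool, params$pool[[b]]$beta,
                             params$pool[[b]]$bias, arch$activation)
    caches[[b]] <- list(conv = cv, pool = pl)
    x <- pl$y
  }
  flat <- x
  dim(flat) <- c(n, arch$flat)
  en <- dense_forward(flat, params$enc$W, params$enc$b, arch$activation)
  list(z = en$y, caches = caches, enc = en, flat_dim = dim(x))
}

## dz: gradient at the latent code; returns parameter grads and nothing below
encoder_backward <- function(dz, fwd, arch, params) {
  B <- length(arch$blocks)
  den <- dense_backward(dz, fwd$enc$y, fwd$enc$cache)
  g <- list(conv = vector("list", B), pool = vector("list", B),
            enc = list(W = den$dW, b = den$db))
  dx <- den$dx
  dim(dx) <- fwd$flat_dim
  for (b in rev(seq_len(B))) {
    cc <- fwd$caches[[b]]
    pb <- pool_layer_backward(dx, cc$pool$y, cc$pool$cache)
    cb <- conv1d_layer_backward(pb$dx, cc$conv$y, cc$conv$cache)
    g$pool[[b]] <- list(beta = pb$dbeta, bias = pb$dbias)
    g$conv[[b]] <- list(W = cb$dW, b = cb$db)
    dx <- cb$dx
  }
  g
}

decoder_forward <- function(z, arch, params) {
  if (arch$padding != "same")
    fail("the decoder mirror is defined for same padding only")
  n <- nrow(z)
  B <- length(arch$blocks)
  de <- dense_forward(z, params$dec$W, params$dec$b, arch$activation)
  last <- arch$blocks[[B]]
  x <- de$y
  dim(x) <- c(n, last$len_pool, last$filters)
  caches <- vector("list", B)
  for (b in rev(seq_len(B))) {
    i <- arch$blocks[[b]]
    up <- upsample_forward(x, i$pool, i$len_conv)
    actn <- if (b == 1L) "identity" else arch$activation
    cv <- conv1d_layer_forward(up, params$deconv[[b]]$W, params$deconv[[b]]$b,
                               actn, "same")
    caches[[b]] <- list(cv = cv, L2 = dim(x)[2], pool = i$pool)
    x <- cv$y
  }
  xhat <- x
  dim(xhat) <- c(n, arch$input_len)
  list(xhat = xhat, caches = caches, dec = de)
}

decoder_backward <- function(dxhat, fwd, arch, params) {
  n <- nrow(dxhat)
  B <- length(arch$blocks)
  dx <- array(dxhat, c(n, arch$input_len, 1L))
  g <- list(deconv = vector("list", B))
  for (b in seq_len(B)) {
    cc <- fwd$caches[[b]]
    cb <- conv1d_layer_backward(dx, cc$cv$y, cc$cv$cache)
    g$deconv[[b]] <- list(W = cb$dW, b = cb$db)
    dx <- upsample_backward(cb$dx, cc$pool, cc$L2)
  }
  dflat <- dx
  dim(dflat) <- c(n, arch$flat)
  den <- dense_backward(dflat, fwd$dec$y, fwd$dec$cache)
  g$dec <- list(W = den$dW, b = den$db)
  g$dz <- den$dx
  g
}

## zero-filled gradient skeleton matching the parameter structure
zero_like <- function(p) rapply(p, function(m) m * 0, how = "replace")

## reconstruction loss and its parameter gradient for the full autoencoder
cae_ae_grad <- function(params, arch, X) {
  ef <- encoder_forward(X, arch, params)
  df <- decoder_forward(ef$z, arch, params)
  loss <- reconstruction_loss(X, df$xhat)
  dxhat <- 2 * (df$xhat - X) / length(X)
  gd <- decoder_backward(dxhat, df, arch, params)
  ge <- encoder_backward(gd$dz, ef, arch, params)
  g <- zero_like(params)
  g$conv <- ge$conv; g$pool <- ge$pool; g$enc <- ge$enc
  g$dec <- gd$dec; g$deconv <- gd$deconv
  list(loss = loss, grad = g)
}

## cross-entropy loss and gradient for the classifier (head +/- encoder)
cae_clf_grad <- function(params, arch, X, Y1h, encoder_trainable = TRUE) {
  ef <- encoder_forward(X, arch, params)
  hd <- dense_forward(ef$z, params$head$W, params$head$b, "identity")
  prob <- softmax_rows(hd$y)
  loss <- cross_entropy(prob, Y1h)
  dlogits <- (prob - Y1h) / nrow(X)
  hb <- dense_backward(dlogits, hd$y, hd$cache)
  g <- zero_like(params)
  g$head <- list(W = hb$dW, b = hb$db)
  if (encoder_trainable) {
    ge <- encoder_backward(hb$dx, ef, arch, params)
    g$conv <- ge$conv; g$pool <- ge$pool; g$enc <- ge$enc
  }
  list(loss = loss, grad = g, prob = prob)
}

## local autoencoder for one convolution block (greedy pre-training stage):
## conv -> pool -> upsample -> deconv, reconstructing the block input
block_ae_grad <- function(params, arch, b, H) {
  i <- arch$blocks[[b]]
  cv <- conv1d_layer_forward(H, params$conv[[b]]$W, params$conv[[b]]$b,
                             arch$activation, arch$padding)
  pl <- pool_layer_forward(cv$y, i$pool, params$pool[[b]]$beta,
                           params$pool[[b]]$bias, arch$activation)
  up <- upsample_forward(pl$y, i$pool, i$len_conv)
  actn <- if (b == 1L) "identity" else arch$activation
  dc <- conv1d_layer_forward(up, params$deconv[[b]]$W, params$deconv[[b]]$b,
                             actn, "same")
  loss <- reconstruction_loss(H, dc$y)
  dout <- 2 * (dc$y - H) / length(H)
  dcb <- conv1d_layer_backward(dout, dc$y, dc$cache)
  dup <- upsample_backward(dcb$dx, i$pool, i$len_pool)
  plb <- pool_layer_backward(dup, pl$y, pl$cache)
  cvb <- conv1d_layer_backward(plb$dx, cv$y, cv$cache)
  g <- zero_like(params)
  g$conv[[b]] <- list(W = cvb$dW, b = cvb$db)
  g$pool[[b]] <- list(beta = plb$dbeta, bias = plb$dbias)
  g$deconv[[b]] <- list(W = dcb$dW, b = dcb$db)
  list(loss = loss, grad = g)
}

## integer block table handed to the fused compiled training step
arch_blockinfo <- function(arch) {
  do.call(rbind, lapply(arch$blocks, function(b)
    c(b$kernel, b$pool, b$C_in, b$filters, b$len_in, b$len_pool)))
}

## fused compiled version of cae_clf_grad (identical result, one call per
## batch); the per-layer R path above remains the reference implementation
cae_clf_grad_fused <- function(params, arch, X, Y1h, encoder_trainable,
                               zero_skel, blockinfo) {
  res <- .cpp_clf_step(X, Y1h,
                       lapply(params$conv, `[[`, "W"),
                       lapply(params$conv, `[[`, "b"),
                       lapply(params$pool, `[[`, "beta"),
                       lapply(params$pool, `[[`, "bias"),
                       params$enc$W, params$enc$b,
                       params$head$W, params$head$b,
                       blockinfo, act_code(arch$activation),
                       as.integer(arch$padding == "same"),
                       as.integer(encoder_trainable))
  g <- zero_skel
  gr <- res$grads
  g$head <- list(W = gr$headW, b = gr$headB)
  if (encoder_trainable) {
    for (b in seq_along(params$conv)) {
      g$conv[[b]] <- list(W = gr$convW[[b]], b = gr$convB[[b]])
      g$pool[[b]] <- list(beta = gr$poolBeta[[b]], bias = gr$poolBias[[b]])
    }
    g$enc <- list(W = gr$encW, b = gr$encB)
  }
  list(loss = res$loss, grad = g)
}

## fused compiled version of block_ae_grad (identical result, one call per
## batch)
block_ae_grad_fused <- function(params, arch, b, H) {
  i <- arch$blocks[[b]]
  d <- dim(H)
  res <- .cpp_block_ae_step(H, d[1], i$len_in, i$C_in,
                            params$conv[[b]]$W, params$conv[[b]]$b,
                            params$pool[[b]]$beta, params$pool[[b]]$bias,
                            params$deconv[[b]]$W, params$deconv[[b]]$b,
                            i$kernel, i$pool, i$filters, i$len_pool,
                            act_code(arch$activation),
                            as.integer(arch$padding == "same"),
                            act_code(if (b == 1L) "identity" else
                                       arch$activation))
  g <- zero_like(params)
  g$conv[[b]] <- list(W = res$convW, b = res$convb)
  g$pool[[b]] <- list(beta = res$beta, bias = res$bias)
  g$deconv[[b]] <- list(W = res$deconvW, b = res$deconvb)
  list(loss = res$loss, grad = g)
}

## dense latent autoencoder stage on flattened block features
latent_ae_grad <- function(params, arch, Fmat) {
  en <- dense_forward(Fmat, params$enc$W, params$enc$b, arch$activation)
  de <- dense_forward(en$y, params$dec$W, params$dec$b, arch$activation)
  loss <- reconstruction_loss(Fmat, de$y)
  dout <- 2 * (de$y - Fmat) / length(Fmat)
  deb <- dense_backward(dout, de$y, de$cache)
  enb <- dense_backward(deb$dx, en$y, en$cache)
  g <- zero_like(params)
  g$enc <- list(W = enb$dW, b = enb$db)
  g$dec <- list(W = deb$dW, b = deb$db)
  list(loss = loss, grad = g)
}

## ---- flat-vector parameter updates ----------------------------------------

pack_params <- function(p) unlist(p, use.names = FALSE)

unpack_params <- function(theta, skeleton) {
  utils::relist(theta, utils::as.relistable(skeleton))
}

## elementwise combine two parallel parameter structures, leaf by leaf
walk2 <- function(a, b, f) {
  if (is.list(a)) {
    for (k in seq_along(a)) a[[k]] <- walk2(a[[k]], b[[k]], f)
    a
  } else f(a, b)
}

make_updater <- function(optimizer, lr, weight_decay) {
  if (optimizer == "sgd") {
    function(params, grads)
      walk2(params, grads, function(p, g) p - lr * (g + weight_decay * p))
  } else {
    ## Adam keeps flat first/second-moment vectors; the pack/unpack cost is
    ## accepted for the non-default optimizer
    m <- NULL; v <- NULL; t <- 0
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    function(params, grads) {
      theta <- pack_params(params)
      g <- pack_params(grads) + weight_decay * theta
      if (is.null(m)) { m <<- g * 0; v <<- g * 0 }
      t <<- t + 1
      m <<- b1 * m + (1 - b1) * g
      v <<- b2 * v + (1 - b2) * g^2
      mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
      unpack_params(theta - lr * mh / (sqrt(vh) + eps), params)
    }
  }
}

## generic epoch loop: loss_grad(params, rows) -> list(loss, grad)
train_loop <- function(params, loss_grad, n, epochs, control) {
  if (epochs == 0L) return(list(params = params, losses = numeric(0)))
  update <- make_updater(control$optimizer, control$learning_rate,
                         control$weight_decay)
  bs <- max(1L, min(control$batch_size, n))
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    tot <- 0
    for (st in starts) {
      rows <- idx[st:min(st + bs - 1L, n)]
      lg <- loss_grad(params, rows)
      params <- update(params, lg$grad)
      tot <- tot + lg$loss * length(rows)
    }
    losses[ep] <- tot / n
  }
  list(params = params, losses = losses)
}

## ---- training phases -------------------------------------------------------

#' Unsupervised autoencoder pre-training
#'
#' Trains the encoder/decoder pair to minimize mean squared reconstruction
#' error by gradient descent. The default greedy layer-wise schedule trains
#' each convolution block's local autoencoder (conv + pool against upsample +
#' deconvolution) on the frozen representation produced by the blocks before
#' it, then the dense latent autoencoder; `pretrain_mode = "end_to_end"`
#' instead trains the whole autoencoder jointly.
#'
#' @param params parameter list from `cae_init_params()` (internal) or a
#'   previous phase.
#' @param arch a [cae_architecture()].
#' @param X standardized feature matrix (rows = samples).
#' @param control a [cae_control()]; `pretrain_epochs` applies per stage.
#' @return list with updated `params` and a `history` data frame
#'   (`phase`, `stage`, `epoch`, `loss`).
#' @keywords internal
pretrain_autoencoder <- function(params, arch, X, control) {
  epochs <- control$pretrain_epochs
  hist <- list()
  n <- nrow(X)
  if (epochs == 0L)
    return(list(params = params,
                history = data.frame(phase = character(0), stage = character(0),
                                     epoch = integer(0), loss = numeric(0))))
  if (control$pretrain_mode == "end_to_end") {
    res <- train_loop(params,
                      function(p, rows) cae_ae_grad(p, arch, X[rows, , drop = FALSE]),
                      n, epochs, control)
    params <- res$params
    hist[[1]] <- data.frame(phase = "pretrain", stage = "end_to_end",
                            epoch = seq_len(epochs), loss = res$losses)
  } else {
    if (arch$padding != "same")
      fail("autoencoder pre-training requires same padding")
    H <- array(X, c(n, arch$input_len, 1L))
    for (b in seq_along(arch$blocks)) {
      res <- train_loop(params,
                        function(p, rows) block_ae_grad_fused(
                          p, arch, b, H[rows, , , drop = FALSE]),
                        n, epochs, control)
      params <- res$params
      hist[[b]] <- data.frame(phase = "pretrain",
                              stage = paste0("block", b),
                              epoch = seq_len(epochs), loss = res$losses)
      i <- arch$blocks[[b]]
      cv <- conv1d_layer_forward(H, params$conv[[b]]$W, params$conv[[b]]$b,
                                 arch$activation, arch$padding)
      H <- pool_layer_forward(cv$y, i$pool, params$pool[[b]]$beta,
                              params$pool[[b]]$bias, arch$activation)$y
    }
    Fmat <- H
    dim(Fmat) <- c(n, arch$flat)
    res <- train_loop(params,
                      function(p, rows) latent_ae_grad(p, arch,
                                                       Fmat[rows, , drop = FALSE]),
                      n, epochs, control)
    params <- res$params
    hist[[length(hist) + 1]] <- data.frame(phase = "pretrain", stage = "latent",
                                           epoch = seq_len(epochs),
                                           loss = res$losses)
  }
  list(params = params, history = do.call(rbind, hist))
}

#' Supervised fine-tuning of the classification head
#'
#' Trains the softmax head (and, by default, the whole encoder beneath it)
#' with categorical cross-entropy.
#'
#' @inheritParams pretrain_autoencoder
#' @param y_int integer class labels in `1..classes`.
#' @return list with updated `params` and a `history` data frame.
#' @keywords internal
finetune_classifier <- function(params, arch, X, y_int, control) {
  epochs <- control$finetune_epochs
  if (epochs == 0L)
    return(list(params = params,
                history = data.frame(phase = character(0), stage = character(0),
                                     epoch = integer(0), loss = numeric(0))))
  Y1h <- one_hot(y_int, arch$classes)
  blockinfo <- arch_blockinfo(arch)
  if (control$optimizer == "sgd") {
    ## epoch-fused compiled path: R draws the shuffle, C++ runs the batches
    n <- nrow(X)
    bs <- max(1L, min(control$batch_size, n))
    losses <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      res <- .cpp_finetune_epoch(X, Y1h, idx, bs,
                                 lapply(params$conv, `[[`, "W"),
                                 lapply(params$conv, `[[`, "b"),
                                 lapply(params$pool, `[[`, "beta"),
                                 lapply(params$pool, `[[`, "bias"),
                                 params$enc$W, params$enc$b,
                                 params$head$W, params$head$b,
                                 blockinfo, act_code(arch$activation),
                                 as.integer(arch$padding == "same"),
                                 as.integer(control$encoder_trainable),
                                 control$learning_rate, control$weight_decay)
      losses[ep] <- res$loss
      for (b in seq_along(params$conv)) {
        params$conv[[b]] <- list(W = res$convW[[b]], b = res$convB[[b]])
        params$pool[[b]] <- list(beta = res$poolBeta[[b]],
                                 bias = res$poolBias[[b]])
      }
      params$enc <- list(W = res$encW, b = res$encB)
      params$head <- list(W = res$headW, b = res$headB)
    }
    res <- list(params = params, losses = losses)
  } else {
    zero_skel <- zero_like(params)
    res <- train_loop(params,
                      function(p, rows) cae_clf_grad_fused(
                        p, arch, X[rows, , drop = FALSE],
                        Y1h[rows, , drop = FALSE],
                        control$encoder_trainable, zero_skel, blockinfo),
                      nrow(X), epochs, control)
  }
  list(params = res$params,
       history = data.frame(phase = "finetune", stage = "head",
                            epoch = seq_len(epochs), loss = res$losses))
}

## ---- user-facing fit --------------------------------------------------------

#' Fit a 1-D convolutional autoencoder-classifier
#'
#' Two-stage training on fixed-length numeric feature vectors: unsupervised
#' convolutional-autoencoder pre-training (greedy layer-wise by default)
#' followed by supervised fine-tuning of a softmax head on the latent code
#' with categorical cross-entropy. Features are standardized internally; the
#' centering and scaling are stored in the fit and applied by `predict`.
#'
#' @param x feature matrix or data frame (rows = samples), or a formula.
#' @param y class labels (factor, or coercible to one).
#' @param arch a [cae_architecture()]; when `NULL` a default two-block
#'   architecture sized to `ncol(x)` is used.
#' @param control a [cae_control()].
#' @param seed integer seed; the fit is a pure function of
#'   (`x`, `y`, `arch`, `control`, `seed`).
#' @param ... method dispatch arguments; for the formula method, `data`.
#' @return an object of class `"cae"`: architecture, control, fitted
#'   parameters, class `levels`, standardization constants, loss `history`
#'   and final `training_accuracy`.
#' @seealso [predict.cae()], [reconstruct()], [write_cae()], [tune_cae()]
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200 * 6), 200)
#' y <- factor(ifelse(x[, 1] + x[, 2] > 0, "a", "b"))
#' fit <- cae(x, y, control = cae_control(pretrain_epochs = 2,
#'                                        finetune_epochs = 20), seed = 1)
#' mean(predict(fit, x) == y) > 0.8
cae <- function(x, ...) UseMethod("cae")

#' @rdname cae
#' @export
cae.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  feats <- mf[, -1L, drop = FALSE]
  fit <- cae.default(feats, y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname cae
#' @export
cae.default <- function(x, y, arch = NULL, control = cae_control(),
                        seed = 1L, ...) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (anyNA(X)) fail("features contain missing values")
  y <- as.factor(y)
  if (length(y) != nrow(X)) fail("`x` and `y` lengths differ")
  if (nlevels(y) < 2L) {
    ## degenerate single-class problems still fit (and predict that class)
    y <- factor(y, levels = c(levels(y), ".other"))
  }
  if (is.null(arch))
    arch <- cae_architecture(ncol(X), classes = nlevels(y))
  if (arch$input_len != ncol(X)) fail("`arch$input_len` must equal ncol(x)")
  if (arch$classes != nlevels(y))
    fail("`arch$classes` must equal the number of class levels")
  stopifnot(inherits(control, "cae_control"))

  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")

  set.seed(as.integer(seed))
  params <- cae_init_params(arch)
  pre <- pretrain_autoencoder(params, arch, Xs, control)
  fin <- finetune_classifier(pre$params, arch, Xs, as.integer(y), control)

  obj <- structure(list(arch = arch, control = control, params = fin$params,
                        levels = levels(y), center = center, scale = scl,
                        history = rbind(pre$history, fin$history),
                        seed = as.integer(seed), call = match.call()),
                   class = "cae")
  obj$training_accuracy <- mean(predict(obj, X) == y)
  obj
}

#' Predict classes, probabilities or latent codes from a fitted CAE
#'
#' @param object a `"cae"` fit.
#' @param newdata feature matrix or data frame with the same columns the
#'   model was fitted on.
#' @param type `"class"` (default), `"prob"` (softmax probability matrix,
#'   rows summing to 1) or `"latent"` (encoder output).
#' @param ... unused.
#' @return factor of class labels, probability matrix, or latent matrix.
#' @export
predict.cae <- function(object, newdata,
                        type = c("class", "prob", "latent"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (ncol(X) != object$arch$input_len)
    fail("newdata has ", ncol(X), " features; model expects ",
         object$arch$input_len)
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  z <- encoder_forward(Xs, object$arch, object$params)$z
  if (type == "latent") return(z)
  prob <- classify_head(z, object$params$head$W, object$params$head$b)
  if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1L)
  colnames(prob) <- object$levels
  if (type == "prob") return(prob)
  factor(object$levels[max.col(prob, ties.method = "first")],
         levels = object$levels)
}

#' Reconstruct inputs through the autoencoder
#'
#' Passes samples through the fitted encoder and decoder and returns the
#' reconstruction on the original feature scale. Large reconstruction error
#' on new data flags samples unlike the training distribution.
#'
#' @param object a `"cae"` fit.
#' @param newdata feature matrix or data frame.
#' @return numeric matrix of reconstructed features.
#' @export
reconstruct <- function(object, newdata) UseMethod("reconstruct")

#' @export
reconstruct.cae <- function(object, newdata) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  z <- encoder_forward(Xs, object$arch, object$params)$z
  xh <- decoder_forward(z, object$arch, object$params)$xhat
  sweep(sweep(xh, 2, object$scale, "*"), 2, object$center, "+")
}

#' @export
print.cae <- function(x, ...) {
  cat("1-D convolutional autoencoder-classifier\n")
  cat(sprintf("  %d features -> latent %d -> %d classes (%s)\n",
              x$arch$input_len, x$arch$latent, x$arch$classes,
              paste(x$levels, collapse = "/")))
  cat(sprintf("  pre-training: %s, %d epochs/stage; fine-tuning: %d epochs (%s, lr %g)\n",
              x$control$pretrain_mode, x$control$pretrain_epochs,
              x$control$finetune_epochs, x$control$optimizer,
              x$control$learning_rate))
  cat(sprintf("  training accuracy: %.4f\n", x$training_accuracy))
  invisible(x)
}

#' @export
summary.cae <- function(object, ...) {
  h <- object$history
  stages <- unique(h[h$phase == "pretrain", "stage"])
  pre <- vapply(stages, function(s) {
    l <- h[h$stage == s, "loss"]; l[length(l)]
  }, numeric(1))
  out <- list(fit = object, final_pretrain_loss = pre,
              final_finetune_loss = {
                l <- h[h$phase == "finetune", "loss"]
                if (length(l)) l[length(l)] else NA_real_
              },
              n_params = length(pack_params(object$params)))
  class(out) <- "summary.cae"
  out
}

#' @export
print.summary.cae <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  trainable parameters: %d\n", x$n_params))
  if (length(x$final_pretrain_loss))
    cat("  final reconstruction loss per stage:\n")
  for (s in names(x$final_pretrain_loss))
    cat(sprintf("    %-10s %.6g\n", s, x$final_pretrain_loss[s]))
  if (!is.na(x$final_finetune_loss))
    cat(sprintf("  final classification loss: %.6g\n", x$final_finetune_loss))
  invisible(x)
}

#' @export
coef.cae <- function(object, ...) object$params

#' Plot CAE training curves
#'
#' Loss against epoch for every training stage (reconstruction losses for the
#' pre-training stages, cross-entropy for fine-tuning).
#'
#' @param x a `"cae"` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cae <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) { warning("no training history to plot"); return(invisible(x)) }
  stages <- unique(h$stage)
  graphics::plot(NULL, xlim = range(h$epoch), ylim = range(h$loss),
                 xlab = "epoch", ylab = "loss", ...)
  for (k in seq_along(stages)) {
    hh <- h[h$stage == stages[k], ]
    graphics::lines(hh$epoch, hh$loss, col = k, lty = k)
  }
  graphics::legend("topright", legend = stages, col = seq_along(stages),
                   lty = seq_along(stages), bty = "n")
  invisible(x)
}

#' Export training curves as CSV
#'
#' @param object a `"cae"` fit.
#' @param file destination path.
#' @return the history data frame, invisibly.
#' @export
write_training_curves <- function(object, file) {
  stopifnot(inherits(object, "cae"))
  utils::write.csv(object$history, file, row.names = FALSE)
  invisible(object$history)
}
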