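## ---------------------------------------------------------------------------
## 1-D layer primitives. Feature maps are arrays (n, L, C): sample, position,
## channel. Convolutions use the cross-correlation convention, stride 1, via
## im2col matrix multiplication; all backward passes are hand-derived and
## checked against central finite differences in the test suite.
## ---------------------------------------------------------------------------

act_forward <- function(z, activation) {
  switch(activation, tanh = tanh(z), identity = z,
         fail("unknown activation: ", activation))
}
## derivative expressed through the activation *output* y
act_deriv <- function(y, activation) {
  switch(activation, tanh = 1 - y^2, identity = 1,
         fail("unknown activation: ", activation))
}

#' One-dimensional convolution layer (cross-correlation, stride 1)
#'
#' Each output map j is `f(sum_i x_i * k_ij + b_j)`: every input channel is
#' correlated with its kernel slice, the results are summed, a per-map bias is
#' added and the activation applied. The workhorse of the encoder; exported in
#' a plain-vector form for direct use and testing.
#'
#' @param signal numeric vector (one channel) or an `(n, L, C)` array of
#'   feature maps.
#' @param kernels a numeric vector (single kernel), an `s x m` matrix (one
#'   column per output map, single input channel), or an `(s * C_in) x m`
#'   matrix for multi-channel input with kernel taps ordered tap-major
#'   (tap 1 channels, tap 2 channels, ...).
#' @param bias per-output-map bias, recycled to the number of maps.
#' @param activation `"identity"` (default) or `"tanh"`.
#' @param padding `"valid"` (output length `L - s + 1`) or `"same"`
#'   (zero-padded, output length `L`).
#' @return for vector input, a vector (one map) or `L_out x m` matrix;
#'   for array input, an `(n, L_out, m)` array.
#' @export
#' @examples
#' conv1d_forward(c(1, 2, 3), c(1, 1), bias = 1)          # 4 6
#' conv1d_forward(c(1, 2, 3), 1)                          # identity kernel
conv1d_forward <- function(signal, kernels, bias = 0,
                           activation = "identity", padding = "valid") {
  vec_in <- is.null(dim(signal))
  if (vec_in) signal <- array(signal, c(1L, length(signal), 1L))
  if (is.null(dim(kernels))) kernels <- matrix(kernels, ncol = 1L)
  C_in <- dim(signal)[3]
  if (nrow(kernels) %% C_in != 0L)
    fail("kernel rows must be a multiple of the input channel count")
  b <- rep_len(bias, ncol(kernels))
  out <- conv1d_layer_forward(signal, kernels, b, activation, padding)$y
  if (vec_in) {
    y <- matrix(out, dim(out)[2], dim(out)[3])
    if (ncol(y) == 1L) drop(y) else y
  } else out
}

act_code <- function(activation)
  switch(activation, identity = 0L, tanh = 1L,
         fail("unknown activation: ", activation))

## internal conv forward with cache for backprop (compiled kernel)
conv1d_layer_forward <- function(x, W, b, activation, padding) {
  d <- dim(x); n <- d[1]; L <- d[2]; C_in <- d[3]
  s <- nrow(W) %/% C_in
  if (nrow(W) %% C_in != 0L) fail("kernel rows incompatible with channels")
  same <- padding == "same"
  if (!same && padding != "valid") fail("unknown padding: ", padding)
  if (s > L)
    fail("kernel longer than signal",
         if (!same) " under valid padding" else "")
  y <- .cpp_conv_fwd(x, n, L, C_in, W, b, act_code(activation),
                     as.integer(same))
  list(y = y,
       cache = list(x = x, W = W, n = n, L = L, C_in = C_in,
                    activation = activation, same = as.integer(same)))
}

conv1d_layer_backward <- function(dy, y, cache) {
  .cpp_conv_bwd(dy, y, cache$x, cache$n, cache$L, cache$C_in, cache$W,
                act_code(cache$activation), cache$same)
}

#' Scaled mean-pool downsampling layer
#'
#' `f(beta * meanpool_n(x) + bias)`: non-overlapping windows of length `n` are
#' averaged, scaled by a learnable per-map factor `beta`, shifted by a
#' learnable bias, and passed through the activation. Output length is
#' `ceiling(L / n)`; when `L` is not a multiple of `n` the final position is
#' replicated to complete the last window.
#'
#' @param x numeric vector (one map) or `(n_samples, L, C)` array.
#' @param n pool window length, a positive integer.
#' @param beta,bias per-map scale and shift, recycled over maps.
#' @param activation `"identity"` (default) or `"tanh"`.
#' @return downsampled map(s), same container shape as the input.
#' @export
#' @examples
#' downsample(c(2, 4), 2)                     # 3
#' downsample(c(1, 2, 3, 4), 2, beta = 2, bias = 1)  # 4 8
downsample <- function(x, n, beta = 1, bias = 0, activation = "identity") {
  if (n < 1 || n != round(n)) fail("pool size `n` must be a positive integer")
  vec_in <- is.null(dim(x))
  if (vec_in) x <- array(x, c(1L, length(x), 1L))
  C <- dim(x)[3]
  out <- pool_layer_forward(x, as.integer(n), rep_len(beta, C),
                            rep_len(bias, C), activation)$y
  if (vec_in) drop(matrix(out, dim(out)[2], dim(out)[3])) else out
}

pool_layer_forward <- function(x, p, beta, bias, activation) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  res <- .cpp_pool_fwd(x, n, L, C, p, beta, bias, act_code(activation))
  list(y = res$y,
       cache = list(m = res$m, p = p, L = L, n = n, C = C, beta = beta,
                    activation = activation))
}

pool_layer_backward <- function(dy, y, cache) {
  .cpp_pool_bwd(dy, y, cache$m, cache$n, cache$L, cache$C, cache$p,
                cache$beta, act_code(cache$activation))
}

## nearest-neighbour upsampling by factor p, then crop to length L_target
upsample_forward <- function(x, p, L_target) {
  d <- dim(x)
  .cpp_upsample_fwd(x, d[1], d[2], d[3], p, L_target)
}

upsample_backward <- function(dy, p, L2) {
  d <- dim(dy)
  .cpp_upsample_bwd(dy, d[1], d[2], d[3], p, L2)
}

dense_forward <- function(x, W, b, activation) {
  z <- x %*% W
  z <- z + matrix(b, nrow(z), ncol(z), byrow = TRUE)
  y <- act_forward(z, activation)
  list(y = y, cache = list(x = x, W = W, activation = activation))
}

dense_backward <- function(dy, y, cache) {
  dz <- dy * act_deriv(y, cache$activation)
  list(dx = tcrossprod(dz, cache$W),
       dW = crossprod(cache$x, dz),
       db = colSums(dz))
}

#' Softmax classification head
#'
#' The output layer stacked on top of the encoder: class scores
#' `softmax(b0 + t(W0) %*% f_v)`. Probabilities are positive and sum to 1.
#'
#' @param f_v flattened feature vector (length p) or an `n x p` matrix of
#'   feature rows.
#' @param W0 `p x T` weight matrix, one column per class.
#' @param b0 length-`T` bias vector.
#' @return probability vector (or `n x T` matrix), rows summing to 1.
#' @export
#' @examples
#' classify_head(c(1, 1), matrix(0, 2, 3), c(0, 0, 0))  # uniform over 3
classify_head <- function(f_v, W0, b0) {
  one <- is.null(dim(f_v))
  x <- if (one) matrix(f_v, 1L) else as.matrix(f_v)
  if (ncol(x) != nrow(W0) || length(b0) != ncol(W0))
    fail("weight shape does not conform to feature length / class count")
  logits <- x %*% W0 + matrix(b0, nrow(x), ncol(W0), byrow = TRUE)
  p <- softmax_rows(logits)
  if (one) drop(p) else p
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Mean squared reconstruction loss
#'
#' `mean((X - Xhat)^2)` over all elements: the autoencoder pre-training
#' objective.
#'
#' @param X input batch (vector or matrix).
#' @param Xhat reconstruction, same shape.
#' @return a non-negative scalar.
#' @export
#' @examples
#' reconstruction_loss(c(1, 2), c(0, 0))  # 2.5
reconstruction_loss <- function(X, Xhat) {
  if (length(X) != length(Xhat) || !identical(dim(X), dim(Xhat)))
    fail("`X` and `Xhat` shapes must match")
  mean((X - Xhat)^2)
}

## cross-entropy on probability rows vs one-hot targets
cross_entropy <- function(prob, onehot) {
  -mean(log(pmax(rowSums(prob * onehot), 1e-300)))
}

one_hot <- function(y_int, n_classes) {
  m <- matrix(0, length(y_int), n_classes)
  m[cbind(seq_along(y_int), y_int)] <- 1
  m
}
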