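## shared fixtures, built in code at test time

## scaled-down version of the default per-task class design
small_design <- function(per_class = 20) {
  soil_design(
    OC_F = c(Low = per_class, Medium = per_class, High = per_class),
    P_F  = c(Low = per_class, Medium = per_class),
    K_F  = c(Low = per_class, Medium = per_class, High = per_class),
    B_F  = c(Low = per_class, Medium = per_class))
}

## wide-margin linearly separable two-class set
separable_xy <- function(n = 200, p = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n)
  shift <- rep(c(-2, 2), length.out = n)
  x[, 1] <- x[, 1] * 0.3 + shift
  list(x = x, y = factor(ifelse(shift > 0, "pos", "neg")))
}

## tiny architecture for gradient checks
tiny_arch <- function(classes = 2)
  cae_architecture(6,
                   blocks = list(list(filters = 3, kernel = 2, pool = 2),
                                 list(filters = 2, kernel = 2, pool = 1)),
                   latent = 2, classes = classes)

soil_features <- c("pH", "EC", "OC", "P", "K", "B", "Fe", "Mn", "Zn", "Cu")

## maximum relative finite-difference error of an analytic gradient
fd_gradient_gap <- function(loss_fun, params, h = 1e-6) {
  theta <- soilcae:::pack_params(params)
  g_analytic <- soilcae:::pack_params(loss_fun(params)$grad)
  g_fd <- numeric(length(theta))
  for (k in seq_along(theta)) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    g_fd[k] <- (loss_fun(soilcae:::unpack_params(tp, params))$loss -
                loss_fun(soilcae:::unpack_params(tm, params))$loss) / (2 * h)
  }
  max(abs(g_analytic - g_fd) / pmax(abs(g_fd), 1e-6))
}
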