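#' Hyperparameter search space for CAE tuning
#'
#' An ordered set of named dimensions, each continuous, log-continuous or
#' integer with bounds. The default space covers the standard CAE knobs:
#' learning rate (log scale), filter counts of the two convolution blocks,
#' kernel size, pool size, latent dimension, fine-tuning epoch budget and
#' batch size.
#'
#' @param dims a data frame with columns `name`, `kind`
#'   (`"continuous" | "log" | "integer"`), `lower`, `upper`; the default is
#'   the standard space described above.
#' @return the validated data frame, classed `"hyperparam_space"`.
#' @export
hyperparam_space <- function(dims = NULL) {
  if (is.null(dims)) {
    dims <- data.frame(
      name  = c("learning_rate", "filters1", "filters2", "kernel",
                "pool", "latent", "finetune_epochs", "batch_size"),
      kind  = c("log", "integer", "integer", "integer",
                "integer", "integer", "integer", "integer"),
      lower = c(1e-4, 4, 4, 2, 1, 2, 20, 16),
      upper = c(1e-1, 32, 32, 5, 2, 8, 200, 128),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(dims),
            all(c("name", "kind", "lower", "upper") %in% names(dims)))
  if (!nrow(dims)) fail("search space needs at least one dimension")
  if (!all(dims$kind %in% c("continuous", "log", "integer")))
    fail("kinds must be continuous, log or integer")
  if (any(dims$lower >= dims$upper)) fail("need lower < upper per dimension")
  if (any(dims$kind == "log" & dims$lower <= 0))
    fail("log dimensions need positive bounds")
  structure(dims, class = c("hyperparam_space", "data.frame"))
}

#' Decode a unit-hypercube point into a named hyperparameter setting
#'
#' Continuous dimensions map affinely, log dimensions geometrically, and
#' integer dimensions by `lower + floor(u * (upper - lower + 1))` clipped to
#' `upper` — so every integer in the range gets an equal share of the unit
#' interval and `u = 1` decodes to `upper`. Decoding is monotone per
#' dimension and exact at both bounds.
#'
#' @param u numeric vector in \[0, 1\], one entry per dimension.
#' @param space a [hyperparam_space()].
#' @return a named list; integer dimensions are integers.
#' @export
#' @examples
#' sp <- hyperparam_space()
#' decode_hyperparams(rep(0, nrow(sp)), sp)$filters1  # lower bound
decode_hyperparams <- function(u, space) {
  if (length(u) != nrow(space)) fail("`u` length must match the space")
  if (any(u < 0 | u > 1)) fail("`u` components must lie in [0, 1]")
  out <- vector("list", nrow(space))
  names(out) <- space$name
  for (k in seq_len(nrow(space))) {
    lo <- space$lower[k]; hi <- space$upper[k]
    out[[k]] <- switch(space$kind[k],
      continuous = lo + u[k] * (hi - lo),
      log        = exp(log(lo) + u[k] * (log(hi) - log(lo))),
      integer    = as.integer(min(hi, floor(lo + u[k] * (hi - lo + 1))))
    )
  }
  out
}

## build architecture + control from a decoded setting; NULL if infeasible
setting_to_model_spec <- function(setting, input_len, classes,
                                  pretrain_epochs = 5) {
  arch <- tryCatch(
    cae_architecture(
      input_len,
      blocks = list(list(filters = setting$filters1, kernel = setting$kernel,
                         pool = setting$pool),
                    list(filters = setting$filters2, kernel = setting$kernel,
                         pool = setting$pool)),
      latent = setting$latent, classes = classes),
    error = function(e) NULL)
  if (is.null(arch)) return(NULL)
  control <- cae_control(learning_rate = setting$learning_rate,
                         batch_size = setting$batch_size,
                         pretrain_epochs = pretrain_epochs,
                         finetune_epochs = setting$finetune_epochs)
  list(arch = arch, control = control)
}

setting_key <- function(setting)
  paste(vapply(setting, function(v) format(v, digits = 15), character(1)),
        collapse = "|")

#' Validation-error fitness of a hyperparameter setting
#'
#' Trains a CAE with the decoded setting on a stratified 80/20 split of the
#' supplied training data and returns `1 - validation accuracy`, the quantity
#' the optimizer minimizes. Results are cached by decoded setting, and the
#' per-evaluation training seed is fixed from the master seed, so fitness is
#' deterministic. Settings whose decoded architecture is infeasible (e.g. the
#' kernel outgrows the feature map) score a soft penalty of 1 instead of
#' failing the search.
#'
#' @param setting named list as returned by [decode_hyperparams()].
#' @param x,y training features and labels.
#' @param seed master seed; the internal split and training seeds derive
#'   from it.
#' @param cache optional environment used as a memo table.
#' @param val_fraction validation share of the split (default 0.2).
#' @param pretrain_epochs pre-training epochs used for every evaluation.
#' @return error rate in \[0, 1\].
#' @export
evaluate_fitness <- function(setting, x, y, seed = 1L, cache = NULL,
                             val_fraction = 0.2, pretrain_epochs = 5) {
  key <- setting_key(setting)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  y <- as.factor(y)
  spec <- setting_to_model_spec(setting, ncol(as.matrix(x)), nlevels(y),
                                pretrain_epochs)
  if (is.null(spec)) {
    warning("infeasible hyperparameter setting; fitness 1", call. = FALSE)
    fit_val <- 1
  } else {
    idx <- stratified_indices(y, c(train = 1 - val_fraction,
                                   val = val_fraction), seed = seed + 77L)
    xm <- as.matrix(x)
    fit <- cae(xm[idx$train, , drop = FALSE], droplevels(y[idx$train]),
               arch = NULL_if_mismatch(spec$arch, y[idx$train]),
               control = spec$control, seed = seed + 101L)
    pred <- predict(fit, xm[idx$val, , drop = FALSE])
    fit_val <- 1 - mean(as.character(pred) == as.character(y[idx$val]))
  }
  if (!is.null(cache)) cache[[key]] <- fit_val
  fit_val
}

## the split can drop a level in pathological tiny cases; rebuild arch then
NULL_if_mismatch <- function(arch, y_sub) {
  k <- nlevels(droplevels(as.factor(y_sub)))
  if (k == arch$classes) arch
  else cae_architecture(arch$input_len,
                        blocks = lapply(arch$blocks, function(b)
                          list(filters = b$filters, kernel = b$kernel,
                               pool = b$pool)),
                        latent = arch$latent, classes = max(k, 2L),
                        activation = arch$activation, padding = arch$padding)
}

#' Tune CAE hyperparameters with the chaotic Reptile Search optimizer
#'
#' Runs [erso()] over the unit hypercube, decoding each candidate with
#' [decode_hyperparams()] and scoring it with [evaluate_fitness()]
#' (validation error on a stratified internal split). The best setting is
#' then used to retrain a final model on the full supplied data.
#'
#' @param x,y training features and labels (the tuner makes its own internal
#'   validation split).
#' @param space a [hyperparam_space()].
#' @param control an [erso_control()]; the default desk-scale budget is
#'   `N = 10` candidates for `T_max = 20` iterations.
#' @param seed master seed driving the search, the split and every training.
#' @param pretrain_epochs pre-training epochs per evaluation.
#' @return an object of class `"cae_tune"`: `best_setting`, `best_fitness`
#'   (validation error), the final retrained `model`, the full evaluation
#'   `log` (one row per distinct setting evaluated), `n_trainings`, and the
#'   underlying `optimizer` result.
#' @export
tune_cae <- function(x, y, space = hyperparam_space(),
                     control = erso_control(N = 10, T_max = 20),
                     seed = 1L, pretrain_epochs = 5) {
  y <- as.factor(y)
  d <- nrow(space)
  cache <- new.env(parent = emptyenv())
  log_env <- new.env(parent = emptyenv())
  log_env$rows <- list()
  n_train <- 0L
  objective <- function(u) {
    setting <- decode_hyperparams(u, space)
    key <- setting_key(setting)
    hit <- !is.null(cache[[key]])
    f <- evaluate_fitness(setting, x, y, seed = seed, cache = cache,
                          pretrain_epochs = pretrain_epochs)
    if (!hit) {
      n_train <<- n_train + 1L
      log_env$rows[[length(log_env$rows) + 1L]] <-
        c(list(fitness = f), setting)
    }
    f
  }
  opt <- erso(objective, lower = rep(0, d), upper = rep(1, d),
              control = control, seed = seed)
  best_setting <- decode_hyperparams(opt$par, space)
  spec <- setting_to_model_spec(best_setting, ncol(as.matrix(x)), nlevels(y),
                                pretrain_epochs)
  if (is.null(spec)) fail("best candidate decoded to an infeasible setting")
  model <- cae(as.matrix(x), y, arch = spec$arch, control = spec$control,
               seed = seed + 202L)
  log_df <- do.call(rbind, lapply(log_env$rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  structure(list(best_setting = best_setting, best_fitness = opt$value,
                 model = model, log = log_df, n_trainings = n_train,
                 optimizer = opt, space = space, seed = seed),
            class = "cae_tune")
}

#' @export
print.cae_tune <- function(x, ...) {
  cat("ERSO-tuned CAE\n")
  cat(sprintf("  evaluations: %d distinct settings trained (%d objective calls)\n",
              x$n_trainings, x$optimizer$evaluations))
  cat(sprintf("  best validation error: %.4f\n", x$best_fitness))
  cat("  best setting:\n")
  for (nm in names(x$best_setting))
    cat(sprintf("    %-16s %s\n", nm, format(x$best_setting[[nm]])))
  invisible(x)
}

#' Export the tuning evaluation log as CSV
#'
#' @param object a `"cae_tune"` result.
#' @param file destination path.
#' @return the log data frame, invisibly.
#' @export
write_tuning_log <- function(object, file) {
  stopifnot(inherits(object, "cae_tune"))
  utils::write.csv(object$log, file, row.names = FALSE)
  invisible(object$log)
}
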