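#' Experiment configuration
#'
#' Everything a full run needs: the data source (synthetic design or a CSV
#' path), the task list, the fine-tuning epoch grid, the split fractions, the
#' tuner settings, and one master seed from which every stage's seed is
#' derived.
#'
#' @param data_source `"synthetic"` or `"csv"`.
#' @param csv_path dataset path when `data_source = "csv"`.
#' @param design,generator synthetic-data settings ([soil_design()],
#'   [soil_generator_config()]).
#' @param tasks label columns to classify (default all five).
#' @param epochs fine-tuning epoch grid; each task is evaluated once per
#'   setting (default 500/1000/1500/2000).
#' @param split named fractions (default stratified 70/10/20
#'   train/validation/test).
#' @param tune logical: run the hyperparameter search per task (once, reused
#'   across the epoch grid) or use the default architecture.
#' @param tuner_N,tuner_T search budget of [tune_cae()].
#' @param space a [hyperparam_space()].
#' @param pretrain_epochs pre-training epochs for every model trained.
#' @param seed master seed.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return a list of class `"experiment_config"`.
#' @export
experiment_config <- function(data_source = c("synthetic", "csv"),
                              csv_path = NULL,
                              design = soil_design(),
                              generator = soil_generator_config(),
                              tasks = soil_task_names(),
                              epochs = c(500, 1000, 1500, 2000),
                              split = c(train = 0.7, validation = 0.1,
                                        test = 0.2),
                              tune = TRUE, tuner_N = 10, tuner_T = 20,
                              space = hyperparam_space(),
                              pretrain_epochs = 5,
                              seed = 1L, out_dir = NULL) {
  data_source <- match.arg(data_source)
  if (data_source == "csv" && is.null(csv_path))
    fail("`csv_path` is required when data_source = 'csv'")
  if (!length(tasks)) fail("`tasks` must be non-empty")
  bad <- setdiff(tasks, soil_task_names())
  if (length(bad)) fail("unknown task(s): ", paste(bad, collapse = ", "))
  if (any(epochs <= 0)) fail("epoch settings must be positive")
  if (abs(sum(split) - 1) > 1e-8) fail("split fractions must sum to 1")
  if (!all(c("train", "test") %in% names(split)))
    fail("split must name at least train and test fractions")
  structure(list(data_source = data_source, csv_path = csv_path,
                 design = design, generator = generator, tasks = tasks,
                 epochs = as.integer(epochs), split = split,
                 tune = isTRUE(tune), tuner_N = as.integer(tuner_N),
                 tuner_T = as.integer(tuner_T), space = space,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Keys mirror the arguments of [experiment_config()]; `design` entries are
#' named count maps, `generator` accepts `margin`, `noise_scale`,
#' `correlation`, `include_micro`, and `space` is a list of
#' `{name, kind, lower, upper}` records. Omitted keys keep their defaults.
#'
#' @param file YAML path.
#' @return an `"experiment_config"`.
#' @export
read_experiment_config <- function(file) {
  y <- yaml::read_yaml(file)
  args <- list()
  for (k in c("data_source", "csv_path", "tasks", "epochs", "tune",
              "tuner_N", "tuner_T", "pretrain_epochs", "seed", "out_dir"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$split)) args$split <- unlist(y$split)
  if (!is.null(y$design))
    args$design <- do.call(soil_design, lapply(y$design, unlist))
  if (!is.null(y$generator))
    args$generator <- do.call(soil_generator_config, y$generator)
  if (!is.null(y$space))
    args$space <- hyperparam_space(do.call(rbind, lapply(y$space, function(d)
      data.frame(name = d$name, kind = d$kind, lower = d$lower,
                 upper = d$upper, stringsAsFactors = FALSE))))
  do.call(experiment_config, args)
}

## deterministic per-stage seed derivation from the master seed
derive_seed <- function(master, task_index, stage, epoch_index = 0L) {
  offset <- switch(stage, data = 0L, tune = 100L, train = 200L,
                   split = 300L, fail("unknown stage"))
  (as.integer(master) + 7919L * task_index + offset + epoch_index) %% 2000000000L
}

#' Run the full soil-classification experiment
#'
#' Data generation (or CSV ingestion), then per task: a stratified
#' train/validation/test split, one hyperparameter search (optional), and one
#' model per fine-tuning epoch setting trained on train+validation and
#' evaluated on the held-out test split. Emits the metric report, confusion
#' matrices and a run manifest; the whole run is a pure function of
#' (`config`, master seed).
#'
#' @param config an [experiment_config()].
#' @return an object of class `"soil_experiment"`: the `report`
#'   ([build_report()] output), nested `confusions`, per-task
#'   `tuning` results, per-task test `accuracy` (percent, by epoch setting),
#'   and the `manifest`.
#' @export
run_soil_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  data <- if (config$data_source == "synthetic") {
    generate_soil_data(config$design, config$generator,
                       seed = derive_seed(config$seed, 0L, "data"))
  } else {
    load_dataset_csv(config$csv_path, config$generator)
  }
  for (task in config$tasks)
    if (!task %in% names(data)) fail("missing label column: ", task)
  feats <- intersect(soil_feature_names(TRUE), names(data))

  confusions <- stats::setNames(
    vector("list", length(config$epochs)),
    as.character(config$epochs))
  for (ep in names(confusions))
    confusions[[ep]] <- list()
  tuning <- list()
  accuracy <- list()
  files <- character(0)

  for (task in config$tasks) {
    ## seeds derive from the task identity, not its position, so task order
    ## never changes a task's results
    ti <- match(task, soil_task_names())
    parts <- train_test_split(data, config$split, stratify_task = task,
                              seed = derive_seed(config$seed, ti, "split"))
    train_val <- rbind(parts$train,
                       if ("validation" %in% names(parts)) parts$validation)
    x_tr <- as.matrix(train_val[, feats, drop = FALSE])
    y_tr <- train_val[[task]]
    x_te <- as.matrix(parts$test[, feats, drop = FALSE])
    y_te <- parts$test[[task]]

    if (config$tune) {
      tuning[[task]] <- tune_cae(
        x_tr, y_tr, space = config$space,
        control = erso_control(N = config$tuner_N, T_max = config$tuner_T),
        seed = derive_seed(config$seed, ti, "tune"),
        pretrain_epochs = config$pretrain_epochs)
      setting <- tuning[[task]]$best_setting
    } else {
      setting <- NULL
    }

    accuracy[[task]] <- stats::setNames(numeric(length(config$epochs)),
                                        as.character(config$epochs))
    for (ei in seq_along(config$epochs)) {
      e <- config$epochs[[ei]]
      if (!is.null(setting)) {
        st <- setting
        st$finetune_epochs <- e
        spec <- setting_to_model_spec(st, ncol(x_tr), nlevels(y_tr),
                                      config$pretrain_epochs)
        arch <- spec$arch; ctrl <- spec$control
      } else {
        arch <- cae_architecture(ncol(x_tr), classes = nlevels(y_tr))
        ctrl <- cae_control(pretrain_epochs = config$pretrain_epochs,
                            finetune_epochs = e)
      }
      fit <- cae(x_tr, y_tr, arch = arch, control = ctrl,
                 seed = derive_seed(config$seed, ti, "train", ei))
      pred <- predict(fit, x_te)
      cm <- confusion_matrix(y_te, pred, labels = levels(y_te))
      confusions[[as.character(e)]][[task]] <- cm
      accuracy[[task]][[as.character(e)]] <-
        100 * mean(as.character(pred) == as.character(y_te))
    }
  }

  report <- build_report(confusions)
  manifest <- list(package = "soilcae",
                   version = as.character(utils::packageVersion("soilcae")),
                   seed = config$seed,
                   config = config[setdiff(names(config), "out_dir")],
                   tasks = config$tasks, epochs = config$epochs,
                   n_samples = nrow(data))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_report(report, config$out_dir, confusions)
    mf <- file.path(config$out_dir, "manifest.json")
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = I(10),
                                force = TRUE), mf)
    files <- c(files, mf)
    manifest$files <- files
  }
  structure(list(report = report, confusions = confusions, tuning = tuning,
                 accuracy = accuracy, manifest = manifest, data = data),
            class = "soil_experiment")
}

#' @export
print.soil_experiment <- function(x, ...) {
  cat("Soil fertility classification experiment\n")
  cat(sprintf("  %d samples, tasks: %s\n", x$manifest$n_samples,
              paste(x$manifest$tasks, collapse = ", ")))
  for (task in names(x$accuracy)) {
    cat(sprintf("  %-9s test accuracy by epochs: %s\n", task,
                paste(sprintf("%s=%.2f%%", names(x$accuracy[[task]]),
                              x$accuracy[[task]]), collapse = "  ")))
  }
  invisible(x)
}
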