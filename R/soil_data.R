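## ---------------------------------------------------------------------------
## Synthetic soil-test-report generator. A dataset is a plain data frame with
## one row per sample: measured features (pH, EC, OC %, available P and K in
## kg/ha, hot-water-extractable B in ppm, optional micronutrients in ppm) and
## five fertility-index labels (OC_F, P_F, K_F, B_F, pH_class) stamped by
## comparing the clean nutrient values to agronomic cut-offs.
## ---------------------------------------------------------------------------

soil_task_names <- function() c("OC_F", "P_F", "K_F", "B_F", "pH_class")

soil_feature_names <- function(include_micro = TRUE) {
  base <- c("pH", "EC", "OC", "P", "K", "B")
  if (include_micro) c(base, "Fe", "Mn", "Zn", "Cu") else base
}

task_nutrient <- c(OC_F = "OC", P_F = "P", K_F = "K", B_F = "B",
                   pH_class = "pH")

#' Per-task class design of a synthetic dataset
#'
#' Target sample counts per fertility class for the four designed nutrient
#' tasks. The default is the reference design: OC 500/500/500, P 500/500,
#' K 500/500/500, B 500/500 — 5,000 samples in total. Every sample carries
#' all five labels; the counts control the block of samples whose value of
#' that task's nutrient is drawn class-conditionally (recorded in the
#' `design_task` column).
#'
#' @param OC_F,P_F,K_F,B_F named count vectors (class name = count).
#' @return a named list of class `"soil_design"`.
#' @export
soil_design <- function(OC_F = c(Low = 500, Medium = 500, High = 500),
                        P_F  = c(Low = 500, Medium = 500),
                        K_F  = c(Low = 500, Medium = 500, High = 500),
                        B_F  = c(Low = 500, Medium = 500)) {
  design <- list(OC_F = OC_F, P_F = P_F, K_F = K_F, B_F = B_F)
  for (task in names(design)) {
    cnt <- design[[task]]
    if (any(cnt < 0) || any(cnt != round(cnt)))
      fail(task, ": counts must be non-negative integers")
    if (is.null(names(cnt)) || any(!nzchar(names(cnt))))
      fail(task, ": counts must be named by class")
  }
  structure(design, class = "soil_design")
}

#' Generator configuration: ranges, cut-offs, noise and correlation
#'
#' Physical ranges and fertility cut-offs per nutrient (defaults follow
#' standard Indian soil-testing conventions: OC % 0.5/0.75, P 11 kg/ha,
#' K 118/280 kg/ha, B 0.5 ppm, pH 6.5/7.5), plus the knobs that control how
#' separable the classes are:
#' \describe{
#'   \item{margin}{fraction of each class interval excluded next to every
#'     cut-off before sampling; larger margins give wider class separation.
#'     Must be below 0.5 (a class interval narrower than twice its margin is
#'     empty).}
#'   \item{noise_scale}{measurement noise standard deviation as a fraction of
#'     the nutrient's physical range, added after labels are stamped — so at
#'     0 the labels are exactly recoverable by thresholding and the label
#'     error rate grows with the noise.}
#'   \item{correlation}{Gaussian-copula correlation between a sample's
#'     features (soils that are rich in one nutrient tend to be rich in
#'     others).}
#' }
#'
#' @param nutrients named list of `list(range =, thresholds =, classes =)`
#'   per measured quantity; labels use `classes` split at `thresholds`.
#' @param margin,noise_scale,correlation see above.
#' @param include_micro include the Fe/Mn/Zn/Cu micronutrient columns.
#' @return a list of class `"soil_generator_config"`.
#' @export
soil_generator_config <- function(nutrients = NULL, margin = 0.1,
                                  noise_scale = 0.02, correlation = 0.2,
                                  include_micro = TRUE) {
  if (is.null(nutrients)) {
    nutrients <- list(
      pH = list(range = c(3.5, 10.5), thresholds = c(6.5, 7.5),
                classes = c("Acidic", "Neutral", "Alkaline")),
      EC = list(range = c(0.1, 4), thresholds = numeric(0), classes = NULL),
      OC = list(range = c(0.1, 1.5), thresholds = c(0.5, 0.75),
                classes = c("Low", "Medium", "High")),
      P  = list(range = c(2, 30), thresholds = 11,
                classes = c("Low", "Medium")),
      K  = list(range = c(30, 500), thresholds = c(118, 280),
                classes = c("Low", "Medium", "High")),
      B  = list(range = c(0.05, 1.5), thresholds = 0.5,
                classes = c("Low", "Medium")),
      Fe = list(range = c(2, 40), thresholds = numeric(0), classes = NULL),
      Mn = list(range = c(1, 20), thresholds = numeric(0), classes = NULL),
      Zn = list(range = c(0.2, 5), thresholds = numeric(0), classes = NULL),
      Cu = list(range = c(0.2, 5), thresholds = numeric(0), classes = NULL)
    )
  }
  for (nm in names(nutrients)) {
    nu <- nutrients[[nm]]
    if (length(nu$thresholds) &&
        (any(diff(c(nu$range[1], nu$thresholds, nu$range[2])) <= 0)))
      fail(nm, ": thresholds must be strictly increasing inside the range")
  }
  if (noise_scale < 0) fail("`noise_scale` must be >= 0")
  if (margin < 0) fail("`margin` must be >= 0")
  if (correlation < 0 || correlation >= 1)
    fail("`correlation` must be in [0, 1)")
  structure(list(nutrients = nutrients, margin = margin,
                 noise_scale = noise_scale, correlation = correlation,
                 include_micro = include_micro),
            class = "soil_generator_config")
}

#' Assign a fertility class by thresholding a measurement
#'
#' `value < t1` is the first class, `t1 <= value < t2` the second, and so on;
#' boundaries are inclusive upward (a value exactly at a cut-off gets the
#' higher class). Two-class tasks use a single cut-off.
#'
#' @param value numeric measurement(s); must be finite.
#' @param thresholds strictly increasing cut-offs.
#' @param labels class labels, `length(thresholds) + 1` of them; defaults to
#'   Low/Medium (one cut-off) or Low/Medium/High (two).
#' @return factor of class labels with `labels` as levels.
#' @export
#' @examples
#' assign_fertility_class(c(0.3, 0.5, 0.9), c(0.5, 0.75))
assign_fertility_class <- function(value, thresholds, labels = NULL) {
  if (any(!is.finite(value))) fail("`value` must be finite")
  if (is.unsorted(thresholds, strictly = TRUE)) fail("thresholds must increase")
  if (is.null(labels))
    labels <- c("Low", "Medium", "High")[seq_len(length(thresholds) + 1L)]
  if (length(labels) != length(thresholds) + 1L)
    fail("need one more label than thresholds")
  idx <- rowSums(outer(value, thresholds, ">=")) + 1L
  factor(labels[idx], levels = labels)
}

## inverse-CDF truncated normal centred in [a, b], driven by uniforms u
truncnorm_from_u <- function(u, a, b) {
  mu <- (a + b) / 2
  sd <- max((b - a) / 4, 1e-12)
  plo <- stats::pnorm(a, mu, sd); phi <- stats::pnorm(b, mu, sd)
  stats::qnorm(plo + u * (phi - plo), mu, sd)
}

#' Generate a synthetic soil-test-report dataset
#'
#' Builds the designed per-task blocks (each block's nutrient drawn from its
#' class-conditional truncated Gaussian, a margin away from the cut-offs),
#' fills every other feature from balanced class-conditional or background
#' draws coupled through a Gaussian copula, adds measurement noise, and
#' stamps all five labels by thresholding the clean values. Class counts per
#' designed block are honoured exactly for every seed; with `noise_scale = 0`
#' thresholding the emitted features reproduces the stamped labels exactly.
#'
#' @param design a [soil_design()].
#' @param config a [soil_generator_config()].
#' @param seed integer seed.
#' @return a data frame (class `"soil_dataset"`): `sample_id`, the feature
#'   columns, the five label factors, and `design_task` recording which
#'   task's block each sample belongs to.
#' @export
#' @examples
#' d <- generate_soil_data(soil_design(OC_F = c(Low = 5, Medium = 5, High = 5),
#'                                     P_F = c(Low = 5, Medium = 5),
#'                                     K_F = c(Low = 5, Medium = 5, High = 5),
#'                                     B_F = c(Low = 5, Medium = 5)), seed = 1)
#' nrow(d)  # 50
generate_soil_data <- function(design = soil_design(),
                               config = soil_generator_config(),
                               seed = 1L) {
  stopifnot(inherits(design, "soil_design"),
            inherits(config, "soil_generator_config"))
  set.seed(as.integer(seed))
  feats <- soil_feature_names(config$include_micro)
  nutrients <- config$nutrients

  ## margin-shrunk sampling interval of one class of one nutrient
  class_interval <- function(nm, class_idx) {
    nu <- nutrients[[nm]]
    cuts <- c(nu$range[1], nu$thresholds, nu$range[2])
    a <- cuts[class_idx]; b <- cuts[class_idx + 1L]
    m <- config$margin * (b - a)
    if (b - a <= 2 * m)
      fail(nm, " class ", class_idx,
           ": interval narrower than twice the margin")
    c(a + m, b - m)
  }

  design_task <- rep(names(design), times = vapply(design, sum, numeric(1)))
  design_class <- unlist(lapply(design, function(cnt)
    rep(names(cnt), times = cnt)), use.names = FALSE)
  n <- length(design_task)
  if (n == 0L) {
    empty <- data.frame(sample_id = integer(0))
    for (f in feats) empty[[f]] <- numeric(0)
    for (task in soil_task_names()) {
      nu <- nutrients[[task_nutrient[[task]]]]
      empty[[task]] <- factor(character(0), levels = nu$classes)
    }
    empty$design_task <- character(0)
    class(empty) <- c("soil_dataset", "data.frame")
    return(empty)
  }

  ## class index per labelled nutrient: designed block value where this is
  ## the block's nutrient, otherwise balanced cycling over the classes
  class_idx <- matrix(0L, n, length(feats), dimnames = list(NULL, feats))
  for (nm in feats) {
    nu <- nutrients[[nm]]
    if (is.null(nu$classes)) next
    designed <- !is.na(match(design_task, names(task_nutrient)[
      task_nutrient == nm]))
    idx <- integer(n)
    if (any(designed))
      idx[designed] <- match(design_class[designed], nu$classes)
    bg <- which(!designed)
    if (length(bg))
      idx[bg] <- rep_len(seq_along(nu$classes), length(bg))
    class_idx[, nm] <- idx
  }

  ## Gaussian copula: one shared factor per sample couples all features
  rho <- config$correlation
  z_shared <- stats::rnorm(n)
  clean <- matrix(NA_real_, n, length(feats), dimnames = list(NULL, feats))
  for (nm in feats) {
    z <- rho * z_shared + sqrt(1 - rho^2) * stats::rnorm(n)
    u <- stats::pnorm(z)
    nu <- nutrients[[nm]]
    if (is.null(nu$classes)) {
      clean[, nm] <- nu$range[1] + u * diff(nu$range)
    } else {
      v <- numeric(n)
      for (k in seq_along(nu$classes)) {
        rows <- which(class_idx[, nm] == k)
        if (!length(rows)) next
        iv <- class_interval(nm, k)
        v[rows] <- truncnorm_from_u(u[rows], iv[1], iv[2])
      }
      clean[, nm] <- v
    }
  }

  ## measurement noise after labelling; clip to the physical range
  observed <- clean
  if (config$noise_scale > 0) {
    for (nm in feats) {
      nu <- nutrients[[nm]]
      observed[, nm] <- clip_to_bounds(
        clean[, nm] + stats::rnorm(n) * config$noise_scale * diff(nu$range),
        nu$range[1], nu$range[2])
    }
  }

  out <- data.frame(sample_id = seq_len(n))
  for (nm in feats) out[[nm]] <- observed[, nm]
  for (task in soil_task_names()) {
    nm <- task_nutrient[[task]]
    nu <- nutrients[[nm]]
    out[[task]] <- assign_fertility_class(clean[, nm], nu$thresholds,
                                          nu$classes)
  }
  out$design_task <- design_task

  ## shuffle rows, then re-number ids
  out <- out[sample.int(n), , drop = FALSE]
  out$sample_id <- seq_len(n)
  rownames(out) <- NULL
  class(out) <- c("soil_dataset", "data.frame")
  out
}

## stratified index split used by the splitter and the tuner
stratified_indices <- function(y, fractions, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (abs(sum(fractions) - 1) > 1e-8) fail("fractions must sum to 1")
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    fail("fractions must be named")
  y <- as.factor(y)
  parts <- lapply(fractions, function(f) integer(0))
  for (cl in levels(y)) {
    rows <- which(y == cl)
    if (!length(rows)) next
    if (length(rows) < length(fractions))
      fail("class ", cl, " has fewer samples (", length(rows),
           ") than partitions (", length(fractions), ")")
    rows <- rows[sample.int(length(rows))]
    n_c <- length(rows)
    exact <- fractions * n_c
    base <- floor(exact)
    rem <- n_c - sum(base)
    if (rem > 0) {
      extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    off <- 0L
    for (k in seq_along(fractions)) {
      take <- rows[seq_len(base[k]) + off]
      parts[[k]] <- c(parts[[k]], take)
      off <- off + base[k]
    }
  }
  lapply(parts, sort)
}

#' Stratified train/validation/test split
#'
#' Partitions a dataset stratified by one task's label: per class, partition
#' sizes are within 1 of the exact proportions (largest-remainder
#' allocation), and partitions are disjoint and exhaustive.
#'
#' @param data a data frame (typically from [generate_soil_data()]).
#' @param fractions named fractions summing to 1, e.g.
#'   `c(train = 0.7, validation = 0.1, test = 0.2)`.
#' @param stratify_task label column to stratify on.
#' @param seed integer seed.
#' @return named list of data frames, one per fraction.
#' @export
train_test_split <- function(data, fractions = c(train = 0.8, test = 0.2),
                             stratify_task = "OC_F", seed = 1L) {
  if (!stratify_task %in% names(data))
    fail("no column named ", stratify_task)
  idx <- stratified_indices(data[[stratify_task]], fractions, seed = seed)
  lapply(idx, function(i) {
    d <- data[i, , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}

## ---- CSV round trip --------------------------------------------------------

#' Write a soil dataset as CSV
#'
#' UTF-8, dot decimal, one row per sample; numeric cells are printed with 17
#' significant digits so a write/read round trip reproduces the data exactly.
#'
#' @param data the dataset data frame.
#' @param file destination path.
#' @return `file`, invisibly.
#' @export
write_soil_csv <- function(data, file) {
  out <- data
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- sprintf("%.17g", out[[nm]])
    else if (is.factor(out[[nm]]))
      out[[nm]] <- as.character(out[[nm]])
  }
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read (and validate) a soil dataset CSV
#'
#' Expects the schema written by [write_soil_csv()]:
#' `sample_id,pH,EC,OC,P,K,B[,Fe,Mn,Zn,Cu],OC_F,P_F,K_F,B_F,pH_class`
#' (plus the optional `design_task` column). Malformed numeric cells raise an
#' error naming the row and column; unknown label values raise an error;
#' unexpected extra columns are kept with a warning.
#'
#' @param file CSV path.
#' @param config a [soil_generator_config()] supplying the label vocabularies.
#' @return a `"soil_dataset"` data frame.
#' @export
read_soil_csv <- function(file, config = soil_generator_config()) {
  if (!file.exists(file)) fail("no such file: ", file)
  raw <- utils::read.csv(file, colClasses = "character", check.names = FALSE)
  required <- c("pH", "EC", "OC", "P", "K", "B", soil_task_names())
  missing <- setdiff(required, names(raw))
  if (length(missing))
    fail("missing required column(s): ", paste(missing, collapse = ", "))
  known <- c("sample_id", soil_feature_names(TRUE), soil_task_names(),
             "design_task")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    warning("ignoring unexpected column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  numeric_cols <- intersect(c("sample_id", soil_feature_names(TRUE)),
                            names(raw))
  out <- raw
  for (nm in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(v) & nzchar(raw[[nm]]))
    if (length(bad))
      fail("malformed numeric cell at row ", bad[1], ", column '", nm, "'")
    if (anyNA(v))
      fail("empty numeric cell at row ", which(is.na(v))[1],
           ", column '", nm, "'")
    out[[nm]] <- v
  }
  if ("sample_id" %in% names(out)) out$sample_id <- as.integer(out$sample_id)
  else out$sample_id <- seq_len(nrow(out))
  for (task in soil_task_names()) {
    nu <- config$nutrients[[task_nutrient[[task]]]]
    vals <- raw[[task]]
    unknown <- setdiff(unique(vals), nu$classes)
    if (length(unknown))
      fail("unknown label value '", unknown[1], "' in column '", task, "'")
    out[[task]] <- factor(vals, levels = nu$classes)
  }
  class(out) <- c("soil_dataset", "data.frame")
  out
}

#' @rdname read_soil_csv
#' @export
load_dataset_csv <- read_soil_csv
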