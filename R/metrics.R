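#' Confusion matrix
#'
#' Counts of true class (rows) against predicted class (columns).
#'
#' @param y_true,y_pred vectors of equal length (factors or characters).
#' @param labels class label order; defaults to the union of levels observed,
#'   in factor-level order. Values outside `labels` raise an error.
#' @return integer matrix of class `"confmat"` with dimnames
#'   `(true, predicted)`.
#' @export
#' @examples
#' confusion_matrix(c("L", "L", "M", "M"), c("L", "M", "M", "M"))
confusion_matrix <- function(y_true, y_pred, labels = NULL) {
  if (length(y_true) == 0L) fail("empty inputs")
  if (length(y_true) != length(y_pred)) fail("length mismatch")
  if (is.null(labels)) {
    labels <- if (is.factor(y_true)) levels(y_true)
              else sort(unique(c(as.character(y_true), as.character(y_pred))))
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  unseen <- setdiff(unique(c(y_true, y_pred)), labels)
  if (length(unseen)) fail("label(s) outside `labels`: ",
                           paste(unseen, collapse = ", "))
  cm <- table(factor(y_true, levels = labels),
              factor(y_pred, levels = labels))
  m <- matrix(as.integer(cm), nrow(cm), ncol(cm),
              dimnames = list(true = labels, predicted = labels))
  structure(m, class = c("confmat", class(m)))
}

#' @export
print.confmat <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted),",
      sum(x), "samples\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class diagonal percentages of a confusion matrix
#'
#' `100 * diagonal / total`: the share of all samples that are correct for
#' each class — the quantity a normalized confusion-matrix plot prints on
#' its diagonal.
#'
#' @param cm a [confusion_matrix()].
#' @return named numeric, rounded half-up to 2 decimals.
#' @export
#' @examples
#' diagonal_percent(structure(matrix(c(495, 10, 5, 490), 2,
#'   dimnames = list(c("Low", "Medium"), c("Low", "Medium"))),
#'   class = c("confmat", "matrix")))
diagonal_percent <- function(cm) {
  total <- sum(cm)
  if (total <= 0) fail("confusion matrix has zero total")
  round_half_up(100 * diag(unclass(cm)) / total, 2)
}

## raw one-vs-rest binary counts for one class
ovr_counts <- function(cm, class) {
  m <- unclass(cm)
  labs <- rownames(m)
  if (!class %in% labs) fail("unknown class: ", class)
  i <- match(class, labs)
  tp <- m[i, i]
  fn <- sum(m[i, ]) - tp
  fp <- sum(m[, i]) - tp
  tn <- sum(m) - tp - fn - fp
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

## ratio with the undefined-denominator convention: 0 with a warning
safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); reported as 0",
            call. = FALSE)
    return(0)
  }
  num / den
}

#' One-vs-rest metric row for one class
#'
#' Binarizes the confusion matrix against `class` (that class versus
#' everything else) and reports binary accuracy, precision, recall, F-score
#' and the Matthews correlation coefficient, each scaled to a percentage.
#' Per-class "accuracy" is one-vs-rest binary accuracy — `(TP + TN) / total`
#' — which is why a 2-class problem prints the same accuracy for both
#' classes. Undefined ratios (a zero denominator) are reported as 0 with a
#' warning. Internal arithmetic is at full precision; rounding (half-up, 2
#' decimals) is applied once at the end and can be disabled.
#'
#' @param cm a [confusion_matrix()].
#' @param class class label to score.
#' @param round round half-up to 2 decimals (default TRUE).
#' @return named numeric: `accuracy`, `precision`, `recall`, `f_score`,
#'   `mcc`, all on the 0–100 scale (`mcc` in -100..100).
#' @export
ovr_metrics <- function(cm, class, round = TRUE) {
  k <- ovr_counts(cm, class)
  tp <- k["tp"]; fn <- k["fn"]; fp <- k["fp"]; tn <- k["tn"]
  total <- tp + fn + fp + tn
  accuracy <- (tp + tn) / total
  precision <- safe_ratio(tp, tp + fp, "precision")
  recall <- safe_ratio(tp, tp + fn, "recall")
  f_score <- if (precision + recall == 0) {
    warning("f_score undefined (zero denominator); reported as 0",
            call. = FALSE)
    0
  } else 2 * precision * recall / (precision + recall)
  mcc_den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- safe_ratio(tp * tn - fp * fn, mcc_den, "mcc")
  out <- 100 * c(accuracy = unname(accuracy), precision = unname(precision),
                 recall = unname(recall), f_score = unname(f_score),
                 mcc = unname(mcc))
  if (round) round_half_up(out, 2) else out
}

#' Unweighted macro average of metric rows
#'
#' The arithmetic mean of each metric over the per-class rows, re-rounded
#' half-up to 2 decimals — the convention behind published "Average" rows,
#' which average the already-rounded class rows.
#'
#' @param rows matrix or data frame of per-class metric rows (columns =
#'   metrics), or a list of named vectors from [ovr_metrics()].
#' @return named numeric of column means, rounded to 2 decimals.
#' @export
macro_average <- function(rows) {
  if (is.list(rows) && !is.data.frame(rows)) rows <- do.call(rbind, rows)
  if (is.null(rows) || !length(rows)) fail("no rows to average")
  rows <- as.matrix(rows)
  if (!nrow(rows)) fail("no rows to average")
  round_half_up(colMeans(rows), 2)
}

#' Full one-vs-rest metrics table for one confusion matrix
#'
#' One row per class plus the macro `Average` row. The average is taken over
#' the full-precision class values and only then rounded: a 2-class table
#' with precisions 98.019802 and 98.989899 prints class rows 98.02 / 98.99
#' and an Average of 98.50 (averaging the already-rounded rows would give
#' 98.51 — not the convention published tables follow).
#'
#' @param cm a [confusion_matrix()].
#' @return data frame of class `"metrics_table"` with columns `class`,
#'   `accuracy`, `precision`, `recall`, `f_score`, `mcc`.
#' @export
metrics_table <- function(cm) {
  labs <- rownames(unclass(cm))
  raw <- t(vapply(labs, function(cl) ovr_metrics(cm, cl, round = FALSE),
                  numeric(5)))
  avg <- macro_average(raw)
  out <- data.frame(class = c(labs, "Average"),
                    rbind(round_half_up(raw, 2), avg), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("metrics_table", "data.frame")
  out
}

#' @export
print.metrics_table <- function(x, ...) {
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], function(v) sprintf("%.2f", v))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Build the full evaluation report
#'
#' Assembles per-task metric tables for every epoch setting, an overall
#' per-epoch summary (the unweighted mean of the task Average rows) and a
#' grand Average row (the mean of the epoch rows), mirroring how multi-epoch
#' evaluation tables are conventionally presented.
#'
#' @param confusions nested named list: `confusions[[epoch]][[task]]` is a
#'   [confusion_matrix()].
#' @return an object of class `"soil_report"`: `tables` (nested list of
#'   [metrics_table()] data frames), `overall` (data frame with one row per
#'   epoch plus `Average`).
#' @export
build_report <- function(confusions) {
  if (!length(confusions)) fail("need at least one epoch of results")
  tables <- lapply(confusions, function(by_task) {
    if (!length(by_task)) fail("need at least one task")
    lapply(by_task, metrics_table)
  })
  epoch_rows <- lapply(tables, function(tt) {
    avgs <- do.call(rbind, lapply(tt, function(tab)
      as.matrix(tab[tab$class == "Average", -1])))
    macro_average(avgs)
  })
  overall <- do.call(rbind, epoch_rows)
  grand <- macro_average(overall)
  overall <- rbind(overall, grand)
  overall <- data.frame(epochs = c(names(confusions), "Average"), overall,
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(tables = tables, overall = overall), class = "soil_report")
}

#' @export
print.soil_report <- function(x, ...) {
  for (ep in names(x$tables)) {
    cat("== epochs:", ep, "==\n")
    for (task in names(x$tables[[ep]])) {
      cat("--", task, "--\n")
      print(x$tables[[ep]][[task]])
    }
  }
  cat("== overall ==\n")
  y <- x$overall
  y[-1] <- lapply(y[-1], function(v) sprintf("%.2f", v))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a report (and its confusion matrices) to disk
#'
#' Emits `report.csv` (long format: epochs, task, class, metrics),
#' `report.json` (the same nested structure as the report object) and one
#' `confusion_<epochs>_<task>.csv` per matrix.
#'
#' @param report a `"soil_report"`.
#' @param dir output directory (created if needed).
#' @param confusions optional: the nested confusion-matrix list used to build
#'   the report; when supplied the matrices are written too.
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(report, dir, confusions = NULL) {
  stopifnot(inherits(report, "soil_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  long <- do.call(rbind, lapply(names(report$tables), function(ep) {
    do.call(rbind, lapply(names(report$tables[[ep]]), function(task) {
      cbind(data.frame(epochs = ep, task = task,
                       stringsAsFactors = FALSE),
            as.data.frame(report$tables[[ep]][[task]]))
    }))
  }))
  f <- file.path(dir, "report.csv")
  utils::write.csv(long, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "overall.csv")
  utils::write.csv(report$overall, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "report.json")
  writeLines(jsonlite::toJSON(list(tables = report$tables,
                                   overall = report$overall),
                              digits = I(10), dataframe = "rows"), f)
  files <- c(files, f)
  if (!is.null(confusions)) {
    for (ep in names(confusions)) for (task in names(confusions[[ep]])) {
      f <- file.path(dir, sprintf("confusion_%s_%s.csv", ep, task))
      utils::write.csv(as.data.frame(unclass(confusions[[ep]][[task]])), f)
      files <- c(files, f)
    }
  }
  invisible(files)
}
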