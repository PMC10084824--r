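## 2x2 matrix used throughout: 500 Low / 500 Medium with 5 and 10 crossings
cm_2x2 <- function() {
  truth <- rep(c("Low", "Medium"), c(500, 500))
  pred <- c(rep("Low", 495), rep("Medium", 5),
            rep("Low", 10), rep("Medium", 490))
  confusion_matrix(truth, pred, labels = c("Low", "Medium"))
}

test_that("confusion matrices count true-by-predicted cells", {
  cm <- confusion_matrix(c("L", "L", "M", "M"), c("L", "M", "M", "M"),
                         labels = c("L", "M"))
  expect_equal(unclass(cm)[, ], matrix(c(1L, 0L, 1L, 2L), 2,
                 dimnames = list(true = c("L", "M"),
                                 predicted = c("L", "M")))[, ])
  expect_equal(sum(cm), 4)
  ## perfect predictions give a diagonal matrix of class counts
  y <- factor(rep(c("a", "b", "c"), c(3, 4, 5)))
  cmp <- confusion_matrix(y, y)
  expect_equal(diag(unclass(cmp)), c(a = 3L, b = 4L, c = 5L))
  expect_equal(sum(unclass(cmp)) - sum(diag(unclass(cmp))), 0L)
  expect_error(confusion_matrix(character(0), character(0)), "empty")
  expect_error(confusion_matrix("a", "b", labels = "a"), "outside")
  expect_error(confusion_matrix(c("a", "a"), "a"), "mismatch")
})

test_that("diagonal percentages match the published worked example", {
  expect_equal(unname(diagonal_percent(cm_2x2())), c(49.50, 49.00))
  y3 <- factor(rep(c("L", "M", "H"), each = 500), levels = c("L", "M", "H"))
  expect_equal(unname(diagonal_percent(confusion_matrix(y3, y3))),
               rep(33.33, 3))
  cm0 <- confusion_matrix(rep(c("a", "b"), each = 3),
                          rep("b", 6), labels = c("a", "b"))
  expect_equal(unname(diagonal_percent(cm0)), c(0, 50))
})

test_that("one-vs-rest rows reproduce the published 2-class table", {
  cm <- cm_2x2()
  expect_equal(unname(ovr_metrics(cm, "Low")),
               c(98.50, 98.02, 99.00, 98.51, 97.00))
  expect_equal(unname(ovr_metrics(cm, "Medium")),
               c(98.50, 98.99, 98.00, 98.49, 97.00))
  ## a perfect matrix scores 100 on every metric
  y <- factor(rep(c("a", "b", "c"), each = 10))
  cmp <- confusion_matrix(y, y)
  for (cl in levels(y))
    expect_equal(unname(ovr_metrics(cmp, cl)), rep(100, 5))
  ## the table's Average row averages full-precision values, then rounds
  tab <- metrics_table(cm)
  expect_equal(unname(unlist(tab[tab$class == "Average", -1])),
               c(98.50, 98.50, 98.50, 98.50, 97.00))
})

test_that("one-vs-rest metrics agree with a brute-force binary oracle", {
  set.seed(5)
  for (rep in 1:1000) {
    k <- sample(2:4, 1)
    m <- matrix(sample(0:30, k * k, replace = TRUE), k)
    if (sum(m) == 0) m[1, 1] <- 1
    labs <- letters[1:k]
    dimnames(m) <- list(labs, labs)
    cm <- structure(m, class = c("confmat", class(m)))
    cl <- sample(labs, 1)
    got <- suppressWarnings(ovr_metrics(cm, cl, round = FALSE))
    ## oracle: rebuild the binarized counts by brute-force enumeration
    tp <- fp <- fn <- tn <- 0
    for (a in labs) for (b in labs) {
      cnt <- m[a, b]
      if (a == cl && b == cl) tp <- tp + cnt
      else if (a == cl) fn <- fn + cnt
      else if (b == cl) fp <- fp + cnt
      else tn <- tn + cnt
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    fsc <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
    want <- 100 * c((tp + tn) / sum(m), prec, rec, fsc, mcc)
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("two-class MCC is symmetric between the classes", {
  set.seed(8)
  for (rep in 1:50) {
    m <- matrix(sample(1:200, 4), 2, dimnames = list(c("x", "y"),
                                                     c("x", "y")))
    cm <- structure(m, class = c("confmat", class(m)))
    expect_equal(ovr_metrics(cm, "x", round = FALSE)[["mcc"]],
                 ovr_metrics(cm, "y", round = FALSE)[["mcc"]],
                 tolerance = 1e-12)
  }
})

test_that("metric bounds and rounding conventions hold", {
  set.seed(13)
  for (rep in 1:100) {
    m <- matrix(sample(0:50, 9, replace = TRUE), 3,
                dimnames = list(letters[1:3], letters[1:3]))
    if (sum(m) == 0) m[2, 2] <- 5
    cm <- structure(m, class = c("confmat", class(m)))
    for (cl in letters[1:3]) {
      v <- suppressWarnings(ovr_metrics(cm, cl))
      expect_true(all(v[c("accuracy", "precision", "recall", "f_score")]
                      >= 0))
      expect_true(all(v[c("accuracy", "precision", "recall", "f_score")]
                      <= 100))
      expect_lte(abs(v[["mcc"]]), 100)
      expect_equal(v, round_half_up(v, 2))
    }
  }
  ## half-up at the second decimal, away from zero
  expect_equal(round_half_up(98.485), 98.49)
  expect_equal(round_half_up(-0.005), -0.01)
  expect_equal(round_half_up(2.675), 2.68)   # binary-representation case
})

test_that("undefined ratios report 0 with a warning", {
  cm <- confusion_matrix(rep("b", 4), rep("b", 4), labels = c("a", "b"))
  w <- capture_warnings(v <- ovr_metrics(cm, "a"))
  expect_true(any(grepl("undefined", w)))
  expect_equal(v[["precision"]], 0)
  expect_equal(v[["recall"]], 0)
})

test_that("diagonal and off-diagonal percentages conserve the total", {
  set.seed(21)
  for (rep in 1:25) {
    m <- matrix(sample(0:99, 9, replace = TRUE), 3,
                dimnames = list(letters[1:3], letters[1:3]))
    if (sum(m) == 0) m[1, 1] <- 1
    cm <- structure(m, class = c("confmat", class(m)))
    offd <- round_half_up(100 * (sum(m) - sum(diag(m))) / sum(m), 2)
    expect_lte(abs(sum(diagonal_percent(cm)) + offd - 100), 0.011 * 4)
  }
})

test_that("macro averages reproduce the published Average rows", {
  ## three-class accuracy column
  expect_equal(unname(macro_average(rbind(
    c(97.93, 96.81, 97.00, 96.90, 95.35),
    c(99.33, 99.00, 99.00, 99.00, 98.50),
    c(98.20, 97.39, 97.20, 97.30, 95.95))))[1], 98.49)
  ## identical rows average to themselves
  r <- c(accuracy = 97.5, precision = 96, recall = 95, f_score = 95.5,
         mcc = 91)
  expect_equal(macro_average(rbind(r, r)), r)
  expect_error(macro_average(list()), "rows")
})

test_that("multi-epoch reports assemble overall and grand-average rows", {
  y <- factor(rep(c("Low", "Medium"), each = 50))
  flip <- function(k) {
    p <- as.character(y)
    p[seq_len(k)] <- "Medium"
    factor(p, levels = levels(y))
  }
  cms <- list("500" = list(B_F = confusion_matrix(y, flip(2))),
              "1000" = list(B_F = confusion_matrix(y, flip(1))))
  rep_ <- build_report(cms)
  expect_named(rep_$tables, c("500", "1000"))
  ## single task: each epoch's overall row equals the task Average row
  for (ep in names(cms)) {
    tab <- rep_$tables[[ep]]$B_F
    expect_equal(unname(unlist(rep_$overall[rep_$overall$epochs == ep, -1])),
                 unname(unlist(tab[tab$class == "Average", -1])))
  }
  ## grand average of the epoch rows
  epoch_rows <- as.matrix(rep_$overall[rep_$overall$epochs != "Average", -1])
  expect_equal(unname(unlist(rep_$overall[rep_$overall$epochs == "Average",
                                          -1])),
               unname(round_half_up(colMeans(epoch_rows), 2)))
  ## CSV round trip of the report values
  dir <- tempfile(); files <- write_report(rep_, dir, cms)
  long <- read.csv(file.path(dir, "report.csv"))
  tab <- rep_$tables[["500"]]$B_F
  expect_equal(long[long$epochs == 500 & long$task == "B_F", "accuracy"],
               tab$accuracy)
})
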