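test_that("fertility classes follow the cut-offs with inclusive-upward bounds", {
  expect_equal(as.character(assign_fertility_class(0.3, c(0.5, 0.75))), "Low")
  expect_equal(as.character(assign_fertility_class(0.5, c(0.5, 0.75))),
               "Medium")
  expect_equal(as.character(assign_fertility_class(0.9, c(0.5, 0.75))), "High")
  expect_equal(as.character(assign_fertility_class(c(5, 11, 30), 11)),
               c("Low", "Medium", "Medium"))
  expect_equal(as.character(assign_fertility_class(7, c(6.5, 7.5),
                 c("Acidic", "Neutral", "Alkaline"))), "Neutral")
  expect_error(assign_fertility_class(NaN, 1), "finite")
  expect_error(assign_fertility_class(1, c(2, 2)), "increase")
})

test_that("generated designs honour class counts exactly for every seed", {
  for (seed in c(1, 7, 123)) {
    d <- generate_soil_data(small_design(12), seed = seed)
    expect_equal(nrow(d), 12 * (3 + 2 + 3 + 2))
    for (task in c("OC_F", "P_F", "K_F", "B_F")) {
      blk <- d[d$design_task == task, ]
      expect_true(all(table(blk[[task]]) == 12))
    }
    ## schema: all features finite, all five labels present on every row
    expect_true(all(is.finite(as.matrix(d[, soil_features]))))
    expect_false(anyNA(d[, c("OC_F", "P_F", "K_F", "B_F", "pH_class")]))
  }
})

test_that("an empty design yields an empty dataset with a valid schema", {
  d <- generate_soil_data(small_design(0), seed = 1)
  expect_equal(nrow(d), 0)
  expect_true(all(c(soil_features, "OC_F", "pH_class") %in% names(d)))
})

test_that("labels are recoverable by thresholding at zero noise", {
  cfg <- soil_generator_config(noise_scale = 0)
  d <- generate_soil_data(small_design(25), cfg, seed = 9)
  nut <- cfg$nutrients
  agree <- function(col, task)
    mean(assign_fertility_class(d[[col]], nut[[col]]$thresholds,
                                nut[[col]]$classes) == d[[task]])
  expect_equal(agree("OC", "OC_F"), 1)
  expect_equal(agree("P", "P_F"), 1)
  expect_equal(agree("K", "K_F"), 1)
  expect_equal(agree("B", "B_F"), 1)
  expect_equal(agree("pH", "pH_class"), 1)
})

test_that("label disagreement grows with the noise scale", {
  for (seed in 1:3) {
    err <- vapply(c(0, 0.05, 0.15, 0.4), function(ns) {
      cfg <- soil_generator_config(noise_scale = ns)
      d <- generate_soil_data(small_design(40), cfg, seed = seed)
      lab <- assign_fertility_class(d$OC, cfg$nutrients$OC$thresholds,
                                    cfg$nutrients$OC$classes)
      mean(lab != d$OC_F)
    }, numeric(1))
    expect_true(all(diff(err) >= 0))
    expect_equal(err[1], 0)
  }
})

test_that("a margin wider than half the class interval is rejected", {
  expect_error(generate_soil_data(small_design(2),
                                  soil_generator_config(margin = 0.5),
                                  seed = 1),
               "margin")
})

test_that("noiseless data is learnable by a single threshold per task", {
  cfg <- soil_generator_config(noise_scale = 0)
  d <- generate_soil_data(small_design(30), cfg, seed = 4)
  ## the generative cut-offs themselves act as a perfect depth-1 stump
  stump <- assign_fertility_class(d$B, cfg$nutrients$B$thresholds,
                                  cfg$nutrients$B$classes)
  expect_equal(mean(stump == d$B_F), 1)
})

test_that("stratified splits are exact, disjoint, exhaustive and seeded", {
  d <- generate_soil_data(small_design(50), seed = 2)
  bf <- d[d$design_task == "B_F", ]     # 50 per class
  parts <- train_test_split(bf, c(train = 0.8, test = 0.2), "B_F", seed = 1)
  expect_equal(nrow(parts$train), 80)
  expect_equal(nrow(parts$test), 20)
  expect_true(all(table(parts$train$B_F) == 40))
  expect_true(all(table(parts$test$B_F) == 10))
  expect_equal(sort(c(parts$train$sample_id, parts$test$sample_id)),
               sort(bf$sample_id))
  ## identity partition
  one <- train_test_split(d, c(all = 1), "OC_F", seed = 3)
  expect_equal(nrow(one$all), nrow(d))
  ## determinism
  p2 <- train_test_split(bf, c(train = 0.8, test = 0.2), "B_F", seed = 1)
  expect_identical(parts$train$sample_id, p2$train$sample_id)
  ## per-class size within 1 of the exact proportion for odd splits
  p3 <- train_test_split(d, c(a = 0.7, b = 0.1, c = 0.2), "K_F", seed = 5)
  for (cl in levels(d$K_F)) {
    n_cl <- sum(d$K_F == cl)
    expect_lte(abs(sum(p3$a$K_F == cl) - 0.7 * n_cl), 1)
    expect_lte(abs(sum(p3$b$K_F == cl) - 0.1 * n_cl), 1)
  }
  ## a class smaller than the partition count errors
  tiny <- d[c(which(d$OC_F == "Low")[1], which(d$OC_F == "Medium")[1:5],
              which(d$OC_F == "High")[1:5]), ]
  expect_error(train_test_split(tiny, c(a = 0.4, b = 0.3, c = 0.3), "OC_F"),
               "fewer samples")
  expect_error(train_test_split(d, c(a = 0.5, b = 0.4), "OC_F"), "sum to 1")
})

test_that("CSV write/read round-trips the dataset exactly", {
  d <- generate_soil_data(small_design(8), seed = 6)
  f <- tempfile(fileext = ".csv")
  write_soil_csv(d, f)
  back <- read_soil_csv(f)
  for (nm in soil_features)
    expect_identical(back[[nm]], d[[nm]])
  for (task in c("OC_F", "P_F", "K_F", "B_F", "pH_class"))
    expect_equal(as.character(back[[task]]), as.character(d[[task]]))
  expect_identical(back$sample_id, d$sample_id)
})

test_that("CSV validation names the offending cell, label or column", {
  d <- generate_soil_data(small_design(3), seed = 1)
  f <- tempfile(fileext = ".csv")
  write_soil_csv(d, f)
  lines <- readLines(f)
  ## malformed numeric cell: row 2, column OC (4th field)
  bad <- lines
  fields <- strsplit(bad[3], ",")[[1]]
  fields[4] <- "oops"
  bad[3] <- paste(fields, collapse = ",")
  fb <- tempfile(fileext = ".csv"); writeLines(bad, fb)
  expect_error(read_soil_csv(fb), "row 2, column 'OC'")
  ## unknown label value
  bad <- lines
  fields <- strsplit(bad[2], ",")[[1]]
  fields[which(strsplit(lines[1], ",")[[1]] == "B_F")] <- "Great"
  bad[2] <- paste(fields, collapse = ",")
  fb2 <- tempfile(fileext = ".csv"); writeLines(bad, fb2)
  expect_error(read_soil_csv(fb2), "unknown label")
  ## extra column warns but loads
  extra <- cbind(d, mystery = 1)
  f3 <- tempfile(fileext = ".csv"); write_soil_csv(extra, f3)
  expect_warning(ok <- read_soil_csv(f3), "mystery")
  expect_equal(nrow(ok), nrow(d))
  ## missing required column errors
  f4 <- tempfile(fileext = ".csv")
  write_soil_csv(d[, setdiff(names(d), "OC")], f4)
  expect_error(read_soil_csv(f4), "missing required")
})
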