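# Dataset container, readers, imputation, normalization, splitting.

test_that("time_series_dataset enforces its invariants", {
  x <- array(rnorm(24), dim = c(2, 3, 4))
  ds <- time_series_dataset(x, labels = c(0L, 1L))
  expect_s3_class(ds, "time_series_dataset")
  expect_identical(dim(ds), c(2L, 3L, 4L))

  expect_error(time_series_dataset(matrix(1, 2, 2)), "3-d array")
  expect_error(time_series_dataset(x, labels = c(0L, 2L)), "0/1")
  expect_error(time_series_dataset(x, feature_names = rep("a", 4)), "unique")
  expect_error(time_series_dataset(x, time_labels = c(3, 2, 1)), "increasing")
  bad <- x; bad[1, 1, 1] <- Inf
  expect_error(time_series_dataset(bad), "finite")
  # NA under a FALSE mask is fine and ignored
  bad[1, 1, 1] <- NA
  m <- !is.na(bad)
  expect_silent(time_series_dataset(bad, mask = m))
})

test_that("read_long_csv handles complete and incomplete panels", {
  df <- expand.grid(id = c("a", "b"), time = 1:3)
  df <- df[order(df$id, df$time), ]
  df$x1 <- seq_len(6); df$x2 <- seq_len(6) * 10; df$label <- c(rep(1L, 3), rep(0L, 3))
  path <- write_long_fixture(df)
  ds <- read_long_csv(path, label_column = "label")
  expect_identical(dim(ds), c(2L, 3L, 2L))
  expect_true(all(ds$mask))
  expect_identical(ds$labels, c(1L, 0L))
  expect_identical(ds$feature_names, c("x1", "x2"))
  # subject a, wave 2, feature x2
  expect_equal(ds$values[1, 2, 2], 20)

  # a subject absent from one wave -> mask-false cells for that whole wave
  path2 <- write_long_fixture(df[df$id != "a" | df$time != 2, ])
  ds2 <- read_long_csv(path2, label_column = "label")
  expect_false(any(ds2$mask[1, 2, ]))
  expect_true(all(ds2$mask[2, , ]))
})

test_that("read_long_csv rejects duplicates and conflicting labels", {
  df <- data.frame(id = c("a", "a"), time = c(1, 1), x = 1:2)
  expect_error(read_long_csv(write_long_fixture(df)), "duplicate.*\\(a, 1\\)")

  df2 <- data.frame(id = c("a", "a"), time = c(1, 2), x = 1:2,
                    label = c(0L, 1L))
  expect_error(read_long_csv(write_long_fixture(df2), label_column = "label"),
               "conflicting labels")
})

test_that("wide CSV reader matches the long reader on the same panel", {
  ds <- make_panel(N = 5, Q = 3, M = 2, seed = 3)
  dir <- withr::local_tempdir()
  wide <- data.frame(id = 1:5,
                     f1__1 = ds$values[, 1, 1], f1__2 = ds$values[, 2, 1],
                     f1__3 = ds$values[, 3, 1],
                     f2__1 = ds$values[, 1, 2], f2__2 = ds$values[, 2, 2],
                     f2__3 = ds$values[, 3, 2],
                     label = ds$labels)
  p <- file.path(dir, "wide.csv")
  data.table::fwrite(wide, p)
  got <- read_wide_csv(p, label_column = "label")
  expect_equal(got$values, ds$values, ignore_attr = TRUE)
  expect_identical(got$labels, ds$labels)
  expect_identical(got$feature_names, c("f1", "f2"))
})

test_that(".ts round-trip preserves values and labels", {
  ds <- make_panel(N = 6, Q = 4, M = 3, seed = 11)
  path <- file.path(withr::local_tempdir(), "toy.ts")
  write_ts_file(ds, path)
  back <- read_ts_file(path)
  expect_equal(back$values, ds$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$labels, ds$labels)
})

test_that(".ts reader parses the dialect and flags ragged series", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.ts")
  writeLines(c("@problemName toy", "@timeStamps false", "@univariate false",
               "@classLabel true 0 1", "@data",
               "1,2,3:4,5,6:0", "7,8,9:10,11,12:1"), p)
  ds <- read_ts_file(p)
  expect_identical(dim(ds), c(2L, 3L, 2L))
  expect_identical(ds$labels, c(0L, 1L))
  expect_equal(ds$values[2, , 1], c(7, 8, 9))

  writeLines(c("@classLabel true 0 1", "@data", "1,2:3,4:0", "1,2,5:3,4,6:1"),
             p)
  expect_error(read_ts_file(p), "ragged|unequal")

  writeLines(c("@bogusTag x", "@classLabel true a b", "@data", "1,2:b"), p)
  expect_warning(ds3 <- read_ts_file(p), "unknown header tag")
  expect_identical(ds3$labels, 1L)  # b is the second @classLabel level
})

test_that("impute_missing implements all three strategies", {
  v <- array(NA_real_, dim = c(2, 2, 1))
  v[1, , 1] <- c(1, NA); v[2, , 1] <- c(3, NA)
  v[2, 2, 1] <- 3
  # feature observed values {1, 3, 3}: subject 1 wave 2 missing
  ds <- time_series_dataset(v)
  out <- impute_missing(ds, "feature_mean")
  expect_true(all(out$mask))
  expect_equal(out$values[1, 2, 1], mean(c(1, 3, 3)))

  # documented worked example: observed {1, 3} -> mean 2
  v2 <- array(c(1, 3, NA, 3), dim = c(2, 2, 1))
  v2[2, 2, 1] <- NA
  ds2 <- time_series_dataset(array(c(1, 3, NA, NA), dim = c(2, 2, 1)))
  out2 <- impute_missing(ds2, "feature_mean")
  expect_equal(out2$values[1, 2, 1], 2)
  expect_equal(out2$values[2, 2, 1], 2)

  # carry forward uses the previous observed wave; wave-0 falls back to mean
  v3 <- array(NA_real_, dim = c(2, 3, 1))
  v3[1, , 1] <- c(5, NA, NA); v3[2, , 1] <- c(NA, 2, NA)
  ds3 <- time_series_dataset(v3)
  out3 <- impute_missing(ds3, "carry_forward")
  expect_equal(out3$values[1, , 1], c(5, 5, 5))
  expect_equal(out3$values[2, 1, 1], mean(c(5, 2)))
  expect_equal(out3$values[2, 3, 1], 2)

  out4 <- impute_missing(ds3, "constant", value = -7)
  expect_equal(out4$values[1, 2, 1], -7)

  # identity on complete data
  full <- make_panel()
  expect_identical(impute_missing(full, "feature_mean"), full)

  # fully missing feature is a named hard error
  v5 <- array(NA_real_, dim = c(2, 2, 2)); v5[, , 1] <- 1
  expect_error(impute_missing(time_series_dataset(v5), "feature_mean"), "V2")
})

test_that("z-score normalizer centers, scales, handles constants, inverts", {
  v <- array(0, dim = c(2, 1, 2))
  v[, 1, 1] <- c(0, 2)   # mean 1, population sd 1
  v[, 1, 2] <- c(5, 5)   # constant
  ds <- time_series_dataset(v)
  st <- fit_normalizer(ds)
  out <- apply_normalizer(ds, st)
  expect_equal(out$values[, 1, 1], c(-1, 1))
  expect_equal(out$values[, 1, 2], c(0, 0))
  expect_equal(st$scale[2], 1)

  ds2 <- make_panel(N = 10, seed = 5)
  st2 <- fit_normalizer(ds2)
  round_trip <- apply_normalizer(apply_normalizer(ds2, st2), st2,
                                 invert = TRUE)
  expect_equal(round_trip$values, ds2$values, tolerance = 1e-10)

  # normalized non-constant features have mean 0, variance 1
  norm <- apply_normalizer(ds2, st2)
  for (m in 1:4) {
    x <- as.vector(norm$values[, , m])
    expect_lt(abs(mean(x)), 1e-8)
    expect_lt(abs(mean(x^2) - 1), 1e-8)
  }
  expect_error(apply_normalizer(make_panel(M = 3), st2), "features")
})

test_that("train_test_split is a deterministic stratified partition", {
  ds <- make_panel(N = 10, seed = 2)
  sp <- train_test_split(ds, 0.8, seed = 4)
  expect_identical(n_subjects <- dim(sp$train)[1], 8L)
  expect_identical(dim(sp$test)[1], 2L)
  # both classes in both splits
  expect_setequal(unique(sp$train$labels), c(0L, 1L))
  expect_setequal(unique(sp$test$labels), c(0L, 1L))
  sp2 <- train_test_split(ds, 0.8, seed = 4)
  expect_identical(sp$train$values, sp2$train$values)
  sp3 <- train_test_split(ds, 0.8, seed = 5)
  expect_false(identical(sp$train$values, sp3$train$values))

  # union = everyone, intersection empty (match rows on a value fingerprint)
  fp <- function(d) apply(d$values, 1, function(r) paste(r, collapse = ","))
  expect_setequal(c(fp(sp$train), fp(sp$test)), fp(ds))
  expect_length(intersect(fp(sp$train), fp(sp$test)), 0)

  expect_error(train_test_split(ds, 1.2, seed = 1), "in \\(0, 1\\)")
  expect_error(train_test_split(make_panel(labels = FALSE), 0.8, seed = 1),
               "labels")
})

test_that("readers produce valid datasets on randomized inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    N <- sample(2:6, 1); Q <- sample(1:4, 1); M <- sample(1:5, 1)
    df <- expand.grid(id = seq_len(N), time = seq_len(Q))
    keep <- runif(nrow(df)) > 0.2
    keep[df$time == 1] <- TRUE  # keep everyone's first wave
    df <- df[keep, ]
    for (m in seq_len(M)) df[[paste0("v", m)]] <- rnorm(nrow(df))
    df$label <- rep_len(c(0L, 1L), N)[df$id]
    ds <- read_long_csv(write_long_fixture(df), label_column = "label")
    expect_silent(validate_time_series_dataset(ds))
    expect_identical(dim(ds), c(N, Q, M))
    # shape is preserved through impute and normalize
    imp <- impute_missing(ds)
    expect_identical(dim(imp), dim(ds))
    expect_identical(dim(apply_normalizer(imp, fit_normalizer(imp))), dim(ds))
  }
})

test_that("filter_subjects drops subjects missing too much", {
  v <- array(1, dim = c(3, 2, 2))
  m <- array(TRUE, dim = c(3, 2, 2))
  m[2, , ] <- FALSE      # subject 2 fully missing
  m[3, 1, 1] <- FALSE    # subject 3 missing 1 of 4 cells
  v[!m] <- NA
  ds <- time_series_dataset(v, mask = m)
  expect_identical(dim(filter_subjects(ds))[1], 3L)          # default keeps all
  expect_identical(dim(filter_subjects(ds, 0.5))[1], 2L)
  expect_identical(dim(filter_subjects(ds, 0))[1], 1L)
})
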