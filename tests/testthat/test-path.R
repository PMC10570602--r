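# Regularization path, importance ranking, top-k selection.

test_that("path terminates empty and is reproducible", {
  gen <- generate_panel(synthetic_spec(n_subjects = 120, n_features = 8,
                                       missing_rate = 0, seed = 3))
  pp <- preprocess_and_split(gen$dataset, 0.8, seed = 3)
  hy <- fast_hyper(seed = 3)
  path <- fit_path(pp$train, pp$test, hy)
  n <- length(path$points)
  expect_length(path$points[[n]]$active_features, 0)
  lambdas <- vapply(path$points, `[[`, 0, "lambda")
  expect_true(all(diff(lambdas) > 0))
  # active set equals the nonzero thetas at every point
  for (pt in path$points)
    expect_identical(pt$active_features, which(pt$theta_snapshot != 0))

  path2 <- fit_path(pp$train, pp$test, hy)
  expect_identical(vapply(path2$points, `[[`, 0, "lambda"), lambdas)
  expect_identical(lapply(path2$points, `[[`, "active_features"),
                   lapply(path$points, `[[`, "active_features"))
  expect_identical(feature_importance(path)$exit_lambda,
                   feature_importance(path2)$exit_lambda)
})

test_that("path terminates even on pure-noise labels", {
  ds <- make_panel(N = 60, Q = 3, M = 6, seed = 8)
  ds$labels <- rep_len(c(0L, 1L), 60)  # labels independent of features
  hy <- fast_hyper(seed = 8, path_multiplier = 2)
  path <- fit_path(ds, NULL, hy)
  expect_length(path$points[[length(path$points)]]$active_features, 0)
})

test_that("feature_importance implements the max-exit-lambda rule", {
  fake <- structure(list(
    points = list(
      list(lambda = 1.0, active_features = c(1L, 2L),
           theta_snapshot = c(0.5, 0.1, 0)),
      list(lambda = 1.02, active_features = c(1L, 2L),
           theta_snapshot = c(0.4, 0.05, 0)),
      list(lambda = 1.0404, active_features = 1L,
           theta_snapshot = c(0.3, 0, 0)),
      list(lambda = 1.0612, active_features = integer(0),
           theta_snapshot = c(0, 0, 0))),
    feature_names = c("a", "b", "c")), class = "lassonet_path")
  rk <- feature_importance(fake)
  expect_equal(unname(rk$exit_lambda), c(1.0404, 1.02, 0))
  expect_identical(rk$order, 1:3)
  # never-active feature is ranked last with exit lambda 0
  expect_identical(unname(rk$rank[3]), 3L)

  # re-entry takes the larger exit
  fake$points[[4]]$active_features <- 2L
  fake$points[[4]]$theta_snapshot <- c(0, 0.01, 0)
  fake$points[[5]] <- list(lambda = 1.0824, active_features = integer(0),
                           theta_snapshot = c(0, 0, 0))
  rk2 <- feature_importance(fake)
  expect_equal(unname(rk2$exit_lambda[2]), 1.0612)

  # exit lambdas invariant to appending post-termination points
  fake$points[[6]] <- list(lambda = 1.104, active_features = integer(0),
                           theta_snapshot = c(0, 0, 0))
  expect_identical(feature_importance(fake)$exit_lambda, rk2$exit_lambda)

  # non-terminated path is a hard error
  bad <- fake; bad$points <- bad$points[1:2]
  expect_error(feature_importance(bad), "not terminated")
})

test_that("ties share a rank and select_k expands across them", {
  rk <- structure(list(
    exit_lambda = c(a = 3, b = 2, c = 2, d = 2, e = 1),
    order = 1:5,
    rank = c(1L, 2L, 2L, 2L, 5L)), class = "importance_ranking")
  expect_identical(as.integer(select_k_features(rk, 1)), 1L)
  s <- select_k_features(rk, 2)  # cuts through the 3-way tie at 2
  expect_setequal(as.integer(s), 1:4)
  expect_true(attr(s, "tie_expanded"))
  s5 <- select_k_features(rk, 5)
  expect_length(s5, 5)
  expect_false(attr(s5, "tie_expanded"))
  expect_error(select_k_features(rk, 6), "\\[1, 5\\]")
})

test_that("export_csv writes path and ranking tables", {
  gen <- generate_panel(synthetic_spec(n_subjects = 80, n_features = 5,
                                       static_relevant = 1L,
                                       temporal_relevant = 4L,
                                       static_effects = 1,
                                       temporal_effects = 1,
                                       missing_rate = 0, seed = 4))
  pp <- preprocess_and_split(gen$dataset, 0.75, seed = 4)
  path <- fit_path(pp$train, pp$test, fast_hyper(seed = 4,
                                                 path_multiplier = 1.5))
  dir <- withr::local_tempdir()
  export_csv(path, file.path(dir, "path.csv"))
  tab <- data.table::fread(file.path(dir, "path.csv"))
  expect_identical(nrow(tab), length(path$points))
  expect_true(all(c("lambda", "n_active", "train_accuracy", "test_auc")
                  %in% names(tab)))
  expect_true(all(tab$train_accuracy >= 0 & tab$train_accuracy <= 1))

  rk <- feature_importance(path)
  export_csv(rk, file.path(dir, "imp.csv"))
  imp <- data.table::fread(file.path(dir, "imp.csv"))
  expect_identical(nrow(imp), 5L)
  expect_identical(names(imp), c("feature", "exit_lambda", "rank"))
})
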