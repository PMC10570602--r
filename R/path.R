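#' Fit the dense-to-sparse regularization path
#'
#' Training proceeds in three stages: (1) dense pretraining — `dense_epochs`
#' of Adam at `lambda = 0` with no proximal step; (2) if
#' `lambda_start = "auto"`, calibration of the first lambda (largest probe
#' lambda screening at most one feature after one epoch, divided by 10);
#' (3) the path proper — for `lambda_k = lambda_start * path_multiplier^k`,
#' warm-started Adam + hierarchical prox with early stopping, one recorded
#' path point per lambda, until every skip coefficient is zero.
#'
#' @param train labeled, imputed, normalized `time_series_dataset`.
#' @param test optional held-out dataset for per-lambda metrics.
#' @param hyper a [lassonet_hyper()] object.
#' @return a `lassonet_path` object: list with `points` (each having
#'   `lambda`, `active_features`, `theta_snapshot`, `train_metrics`,
#'   `test_metrics`, `epochs_run`), `feature_names`, `hyper`,
#'   `lambda_start`, and `params_dense` (the pretrained dense parameters).
#' @export
fit_path <- function(train, test = NULL, hyper = lassonet_hyper()) {
  stopifnot(inherits(train, "time_series_dataset"))
  if (is.null(train$labels)) stop("fit_path requires labeled training data")
  X <- dataset_cube(train)
  y <- as.numeric(train$labels)
  M <- n_features(train)
  Mh <- hyper$hierarchy_multiplier
  adam_metric <- hyper$prox_mode == "adam_metric"

  params <- init_params(hyper, M)
  state <- list()

  # (1) dense pretraining, no penalty, no prox
  if (hyper$dense_epochs > 0) {
    res <- train_cpp(params, state, X, y, 0, hyper$learning_rate,
                     hyper$dense_epochs, hyper$batch_size, Mh,
                     hyper$dense_epochs, FALSE, adam_metric,
                     hyper$positive_weight, path_seed(hyper$seed, 0L))
    params <- res$params
    state <- res$state
  }
  params_dense <- normalize_params(params)

  # (2) lambda_start calibration
  lambda_start <- if (identical(hyper$lambda_start, "auto"))
    calibrate_lambda_start(params, state, X, y, hyper)
  else hyper$lambda_start

  # (3) the path
  points <- list()
  k <- 0L
  repeat {
    lambda <- lambda_start * hyper$path_multiplier^k
    if (lambda > lambda_start * 1e6)
      stop("regularization path failed to terminate: lambda exceeded ",
           "lambda_start * 1e6 with features still active")
    res <- train_cpp(params, state, X, y, lambda, hyper$learning_rate,
                     hyper$epochs_per_lambda, hyper$batch_size, Mh,
                     hyper$patience, TRUE, adam_metric,
                     hyper$positive_weight, path_seed(hyper$seed, k + 1L))
    params <- res$params
    state <- res$state
    act <- which(params$theta != 0)
    points[[length(points) + 1L]] <- list(
      lambda = lambda,
      active_features = act,
      theta_snapshot = as.numeric(params$theta),
      train_metrics = path_metrics(params, X, y),
      test_metrics = if (!is.null(test))
        path_metrics(params, dataset_cube(test), as.numeric(test$labels)),
      epochs_run = res$epochs_run)
    if (!length(act)) break
    k <- k + 1L
  }
  structure(list(points = points, feature_names = train$feature_names,
                 hyper = hyper, lambda_start = lambda_start,
                 params_dense = params_dense),
            class = "lassonet_path")
}

# deterministic per-stage RNG seed, kept below 2^31
path_seed <- function(seed, k) {
  as.integer((as.double(seed) + 1009 * as.double(k)) %% 2147483647)
}

# probe doubling candidates; one epoch each from a cloned state
calibrate_lambda_start <- function(params, state, X, y, hyper) {
  adam_metric <- hyper$prox_mode == "adam_metric"
  cand <- 1e-4
  best <- cand / 10
  for (i in 1:40) {
    res <- train_cpp(params, state, X, y, cand, hyper$learning_rate, 1L,
                     hyper$batch_size, hyper$hierarchy_multiplier, 0L, TRUE,
                     adam_metric, hyper$positive_weight,
                     path_seed(hyper$seed, -1L))
    screened <- sum(res$params$theta == 0)
    if (screened > 1) break
    best <- cand / 10
    cand <- cand * 2
  }
  best
}

path_metrics <- function(params, X, y) {
  logits <- as.numeric(forward_cpp(params, X))
  pred <- as.integer(logits > 0)
  cc <- confusion(y, pred)
  a <- if (length(unique(y)) == 2L) auc(y, logits) else NA_real_
  f <- withCallingHandlers(f1(cc), warning = function(w)
    invokeRestart("muffleWarning"))
  list(accuracy = accuracy(cc), auc = a, f1 = f)
}

#' @export
print.lassonet_path <- function(x, ...) {
  n <- length(x$points)
  cat(sprintf("lassonet_path: %d lambda values from %.4g to %.4g\n",
              n, x$points[[1]]$lambda, x$points[[n]]$lambda))
  cat(sprintf("  %d features; terminal active set size %d\n",
              length(x$feature_names),
              length(x$points[[n]]$active_features)))
  invisible(x)
}

#' Per-feature importance from the path
#'
#' A feature's importance is its exit lambda: the largest lambda at which its
#' skip coefficient was still nonzero (a feature that re-enters and exits
#' again takes the larger value). Features never active on the path get exit
#' lambda 0. Ties share a rank.
#'
#' @param path a terminated `lassonet_path` (last active set empty).
#' @return an `importance_ranking` object with `exit_lambda` (named numeric,
#'   length `M`), `order` (feature indices by decreasing exit lambda) and
#'   `rank` (min-rank, ties shared).
#' @export
feature_importance <- function(path) {
  stopifnot(inherits(path, "lassonet_path"))
  n <- length(path$points)
  if (n == 0 || length(path$points[[n]]$active_features))
    stop("path has not terminated (last active set is non-empty)")
  M <- length(path$feature_names)
  exit_lambda <- numeric(M)
  for (pt in path$points)
    exit_lambda[pt$active_features] <-
      pmax(exit_lambda[pt$active_features], pt$lambda)
  names(exit_lambda) <- path$feature_names
  structure(list(
    exit_lambda = exit_lambda,
    order = order(exit_lambda, decreasing = TRUE),
    rank = rank(-exit_lambda, ties.method = "min")),
    class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  df <- as.data.frame(x)
  cat("importance_ranking (exit lambda, descending):\n")
  print(utils::head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat("  ...", nrow(df) - 10, "more\n")
  invisible(x)
}

#' @export
as.data.frame.importance_ranking <- function(x, ...) {
  data.frame(feature = names(x$exit_lambda)[x$order],
             exit_lambda = unname(x$exit_lambda[x$order]),
             rank = unname(x$rank[x$order]))
}

#' Select the top-k features from an importance ranking
#'
#' Returns the `k` features with the largest exit lambda. When `k` cuts
#' through a tie, all tied features are included and the returned set may be
#' larger than `k` (flagged by the `"tie_expanded"` attribute).
#'
#' @param ranking an `importance_ranking`.
#' @param k number of features, `1 <= k <= M`.
#' @return integer vector of feature indices, with attribute
#'   `"tie_expanded"`.
#' @export
select_k_features <- function(ranking, k) {
  M <- length(ranking$exit_lambda)
  if (!is.numeric(k) || k < 1 || k > M) stop("`k` must be in [1, ", M, "]")
  cutoff <- sort(ranking$exit_lambda, decreasing = TRUE)[k]
  sel <- which(ranking$exit_lambda >= cutoff)
  structure(sel, tie_expanded = length(sel) > k)
}

#' Export a path or ranking as CSV
#'
#' One row per path point (`lambda`, `n_active`, active feature names,
#' train/test metrics), or one row per feature
#' (`feature, exit_lambda, rank`).
#'
#' @param x a `lassonet_path` or `importance_ranking`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path) {
  df <- if (inherits(x, "lassonet_path")) {
    do.call(rbind, lapply(x$points, function(pt) data.frame(
      lambda = pt$lambda,
      n_active = length(pt$active_features),
      active = paste(x$feature_names[pt$active_features], collapse = ";"),
      train_accuracy = pt$train_metrics$accuracy,
      train_auc = pt$train_metrics$auc,
      train_f1 = pt$train_metrics$f1,
      test_accuracy = if (is.null(pt$test_metrics)) NA else
        pt$test_metrics$accuracy,
      test_auc = if (is.null(pt$test_metrics)) NA else pt$test_metrics$auc,
      test_f1 = if (is.null(pt$test_metrics)) NA else pt$test_metrics$f1,
      epochs_run = pt$epochs_run)))
  } else if (inherits(x, "importance_ranking")) {
    as.data.frame(x)
  } else stop("export_csv handles lassonet_path and importance_ranking")
  data.table::fwrite(df, path)
  invisible(path)
}
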