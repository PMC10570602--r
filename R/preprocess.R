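#' Drop subjects with too many unobserved cells
#'
#' The "remove invalid data" step of the preprocessing pipeline, exposed as a
#' row filter: subjects whose fraction of mask-false cells exceeds
#' `max_missing_fraction` are dropped. The default 1.0 keeps everyone.
#'
#' @param ds a `time_series_dataset`.
#' @param max_missing_fraction drop subjects missing strictly more than this
#'   fraction of their `Q * M` cells.
#' @return the filtered dataset.
#' @export
filter_subjects <- function(ds, max_missing_fraction = 1.0) {
  frac <- apply(!ds$mask, 1, mean)
  keep <- which(frac <= max_missing_fraction)
  if (!length(keep)) stop("no subjects left after filtering")
  subset_subjects(ds, keep)
}

#' Impute unobserved cells
#'
#' @param ds a `time_series_dataset`.
#' @param strategy `"feature_mean"` fills each missing cell with the mean of
#'   all observed cells of that feature, pooled over subjects and waves;
#'   `"carry_forward"` uses the subject's previous observed wave, falling
#'   back to the feature mean when the first wave is missing; `"constant"`
#'   fills `value`.
#' @param value fill value for `strategy = "constant"`.
#' @return a dataset with an all-true mask.
#' @export
impute_missing <- function(ds,
                           strategy = c("feature_mean", "carry_forward",
                                        "constant"),
                           value = 0) {
  strategy <- match.arg(strategy)
  values <- ds$values
  mask <- ds$mask
  if (all(mask)) return(ds)
  d <- dim(values)
  if (strategy == "constant") {
    values[!mask] <- value
  } else {
    fmeans <- vapply(seq_len(d[3]), function(m) {
      obs <- values[, , m][mask[, , m]]
      if (!length(obs))
        stop("feature fully missing, cannot impute: ", ds$feature_names[m])
      mean(obs)
    }, numeric(1))
    if (strategy == "feature_mean") {
      for (m in seq_len(d[3])) {
        v <- values[, , m]
        v[!mask[, , m]] <- fmeans[m]
        values[, , m] <- v
      }
    } else {  # carry_forward
      for (m in seq_len(d[3])) {
        v <- values[, , m]
        mk <- mask[, , m]
        v[!mk] <- NA_real_
        if (d[2] >= 1) v[is.na(v[, 1]), 1] <- fmeans[m]
        if (d[2] >= 2) for (q in 2:d[2]) {
          miss <- is.na(v[, q])
          v[miss, q] <- v[miss, q - 1]
        }
        values[, , m] <- v
      }
    }
  }
  time_series_dataset(values, mask = array(TRUE, d), labels = ds$labels,
                      feature_names = ds$feature_names,
                      time_labels = ds$time_labels)
}

#' Fit per-feature normalization statistics
#'
#' Default z-score statistics per feature, pooled over subjects and waves:
#' location = mean, scale = population standard deviation. Constant features
#' get scale exactly 1 (so they normalize to zero). `method = "minmax"` uses
#' location = min, scale = range (again 1 for constant features). Fit on the
#' training split only and reuse on test data.
#'
#' @param ds a fully imputed `time_series_dataset`.
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return a `normalization_stats` object with `location` and `scale`.
#' @export
fit_normalizer <- function(ds, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  if (!all(ds$mask)) stop("normalizer requires a fully imputed dataset")
  d <- dim(ds$values)
  loc <- numeric(d[3]); sc <- numeric(d[3])
  for (m in seq_len(d[3])) {
    x <- as.vector(ds$values[, , m])
    if (method == "zscore") {
      loc[m] <- mean(x)
      sc[m] <- sqrt(mean((x - loc[m])^2))  # population form
    } else {
      loc[m] <- min(x)
      sc[m] <- max(x) - min(x)
    }
    if (sc[m] <= 0) sc[m] <- 1  # degenerate (constant) feature
  }
  structure(list(location = loc, scale = sc, method = method,
                 feature_names = ds$feature_names),
            class = "normalization_stats")
}

#' Apply (or invert) fitted normalization statistics
#'
#' @param ds a `time_series_dataset` with the same `M` the stats were fit on.
#' @param stats a `normalization_stats` object from [fit_normalizer()].
#' @param invert if `TRUE`, undo the transform.
#' @return the transformed dataset.
#' @export
apply_normalizer <- function(ds, stats, invert = FALSE) {
  d <- dim(ds$values)
  if (length(stats$location) != d[3])
    stop("normalization stats were fit for ", length(stats$location),
         " features, dataset has ", d[3])
  values <- ds$values
  for (m in seq_len(d[3])) {
    values[, , m] <- if (invert)
      values[, , m] * stats$scale[m] + stats$location[m]
    else
      (values[, , m] - stats$location[m]) / stats$scale[m]
  }
  time_series_dataset(values, mask = ds$mask, labels = ds$labels,
                      feature_names = ds$feature_names,
                      time_labels = ds$time_labels)
}

#' Stratified subject-level train/test split
#'
#' Deterministic for a given seed. The train split has exactly
#' `floor(N * train_fraction)` subjects; within that budget subjects are
#' allocated per label class by largest remainder, so both classes appear in
#' both splits whenever each class has at least two members.
#'
#' @param ds a labeled `time_series_dataset`.
#' @param train_fraction fraction in (0, 1); default 0.8.
#' @param seed integer seed (required, there is no hidden default RNG use).
#' @return `list(train = ..., test = ...)` of `time_series_dataset`s.
#' @export
train_test_split <- function(ds, train_fraction = 0.8, seed) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)")
  if (is.null(ds$labels)) stop("train_test_split requires labels")
  N <- n_subjects(ds)
  n_train <- floor(N * train_fraction)
  if (n_train < 1L || n_train >= N)
    stop("split would leave an empty train or test set")

  classes <- sort(unique(ds$labels))
  counts <- vapply(classes, function(c) sum(ds$labels == c), 1L)
  exact <- counts * n_train / N
  take <- floor(exact)
  rem <- n_train - sum(take)
  if (rem > 0) {
    ord <- order(exact - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  }
  # keep both classes represented wherever feasible
  for (k in seq_along(classes)) {
    if (counts[k] >= 2L) {
      if (take[k] == 0L) take[k] <- 1L
      if (take[k] == counts[k]) take[k] <- counts[k] - 1L
    }
  }
  over <- sum(take) - n_train
  if (over != 0L) {
    adj <- order(counts, decreasing = TRUE)
    for (k in adj) {
      if (over == 0L) break
      room_down <- take[k] - (if (counts[k] >= 2L) 1L else 0L)
      room_up <- (if (counts[k] >= 2L) counts[k] - 1L else counts[k]) - take[k]
      if (over > 0L && room_down > 0L) {
        d <- min(over, room_down); take[k] <- take[k] - d; over <- over - d
      } else if (over < 0L && room_up > 0L) {
        d <- min(-over, room_up); take[k] <- take[k] + d; over <- over + d
      }
    }
  }
  train_idx <- with_local_seed(seed, {
    unlist(lapply(seq_along(classes), function(k) {
      members <- which(ds$labels == classes[k])
      sample(members, take[k])
    }))
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(N), train_idx)
  list(train = subset_subjects(ds, train_idx),
       test = subset_subjects(ds, test_idx))
}

#' Impute, split and normalize in one call
#'
#' Convenience wrapper running the standard pipeline: impute the full panel,
#' split subjects, fit the normalizer on the training split only, and apply
#' it to both splits.
#'
#' @inheritParams train_test_split
#' @param impute_strategy passed to [impute_missing()].
#' @return `list(train = ..., test = ..., stats = normalization_stats)`.
#' @export
preprocess_and_split <- function(ds, train_fraction = 0.8, seed,
                                 impute_strategy = "feature_mean") {
  ds <- impute_missing(ds, impute_strategy)
  sp <- train_test_split(ds, train_fraction, seed)
  stats <- fit_normalizer(sp$train)
  list(train = apply_normalizer(sp$train, stats),
       test = apply_normalizer(sp$test, stats),
       stats = stats)
}
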