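#' Hyperparameters for the LassoNet-RNN model and its regularization path
#'
#' @param hidden_size hidden width `H` of the recurrent layer.
#' @param hierarchy_multiplier the hierarchy constant `M_hier` of the
#'   constraint `||W_j||_inf <= M_hier * |theta_j|`; `0` reduces the model to
#'   an l1-penalized linear (logistic) model on time-mean features, `Inf`
#'   removes the constraint.
#' @param lambda_start first value of the geometric lambda sequence, or
#'   `"auto"` to calibrate it from the data (largest lambda screening at most
#'   one feature after one epoch, divided by 10).
#' @param path_multiplier geometric growth factor of the lambda sequence
#'   (> 1).
#' @param epochs_per_lambda maximum training epochs at each lambda.
#' @param dense_epochs epochs of unpenalized, unconstrained pretraining.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size (capped at the sample size).
#' @param seed integer seed controlling initialization and batch order.
#' @param patience early-stopping patience, in epochs without improvement of
#'   the penalized training objective.
#' @param prox_mode `"adam_metric"` (default) thresholds the skip
#'   coefficients in the diagonal metric of the Adam step, which preserves
#'   the exact l1 stationarity conditions under Adam; `"lr"` uses the
#'   classical `lambda * learning_rate` threshold of plain proximal gradient
#'   descent.
#' @param positive_weight weight of positive-class samples in the loss
#'   (1 = unweighted).
#' @return a validated `lassonet_hyper` list.
#' @export
lassonet_hyper <- function(hidden_size = 16L, hierarchy_multiplier = 10,
                           lambda_start = "auto", path_multiplier = 1.02,
                           epochs_per_lambda = 100L, dense_epochs = 100L,
                           learning_rate = 1e-3, batch_size = 64L,
                           seed = 1L, patience = 5L,
                           prox_mode = c("adam_metric", "lr"),
                           positive_weight = 1) {
  prox_mode <- match.arg(prox_mode)
  stopifnot(hidden_size >= 1, path_multiplier > 1, epochs_per_lambda >= 1,
            dense_epochs >= 0, learning_rate > 0, batch_size >= 1,
            patience >= 0, positive_weight > 0)
  if (!(identical(lambda_start, "auto") ||
        (is.numeric(lambda_start) && lambda_start > 0)))
    stop("`lambda_start` must be a positive number or \"auto\"")
  if (is.na(hierarchy_multiplier) || hierarchy_multiplier < 0)
    stop("`hierarchy_multiplier` must be >= 0 (possibly Inf)")
  structure(list(
    hidden_size = as.integer(hidden_size),
    hierarchy_multiplier = hierarchy_multiplier,
    lambda_start = lambda_start,
    path_multiplier = path_multiplier,
    epochs_per_lambda = as.integer(epochs_per_lambda),
    dense_epochs = as.integer(dense_epochs),
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    seed = as.integer(seed),
    patience = as.integer(patience),
    prox_mode = prox_mode,
    positive_weight = positive_weight), class = "lassonet_hyper")
}

# (N, Q, M) array -> (N, M, Q) cube expected by the C++ kernels
as_model_cube <- function(values) aperm(values, c(1, 3, 2))

# arma vectors come back from C++ as n x 1 matrices; restore the R layout
normalize_params <- function(p) {
  for (f in c("theta", "hidden_bias", "output_weights", "output_bias",
              "skip_bias"))
    p[[f]] <- as.numeric(p[[f]])
  class(p) <- "lassonet_params"
  p
}

dataset_cube <- function(ds) {
  if (!all(ds$mask)) stop("model input must be fully imputed (mask all TRUE)")
  as_model_cube(ds$values)
}

#' Initialize model parameters
#'
#' Weights are drawn from scaled symmetric uniform distributions,
#' deterministically in `hyper$seed`. Skip coefficients start at small
#' nonzero values (magnitude in `[0.05, 0.15]`, random sign) so that every
#' feature is active at the start of the path; input-weight columns are
#' rescaled where needed so the hierarchy constraint holds at initialization.
#'
#' @param hyper a [lassonet_hyper()] object.
#' @param n_features number of variables `M`.
#' @return a `lassonet_params` list with fields `theta` (length `M`),
#'   `input_weights` (`H x M`), `recurrent_weights` (`H x H`),
#'   `hidden_bias`, `output_weights`, `output_bias`, `skip_bias`.
#' @export
init_params <- function(hyper, n_features) {
  stopifnot(n_features >= 1)
  H <- hyper$hidden_size
  M <- as.integer(n_features)
  p <- with_local_seed(hyper$seed, {
    list(
      theta = sample(c(-1, 1), M, replace = TRUE) * stats::runif(M, 0.05, 0.15),
      input_weights = matrix(stats::runif(H * M, -1, 1) * sqrt(1 / M), H, M),
      recurrent_weights = matrix(stats::runif(H * H, -1, 1) * sqrt(1 / H), H, H),
      hidden_bias = rep(0, H),
      output_weights = stats::runif(H, -1, 1) * sqrt(1 / H),
      output_bias = 0,
      skip_bias = 0)
  })
  Mh <- hyper$hierarchy_multiplier
  if (is.finite(Mh)) {
    for (j in seq_len(M)) {
      cap <- Mh * abs(p$theta[j])
      peak <- max(abs(p$input_weights[, j]))
      if (peak > cap)
        p$input_weights[, j] <- p$input_weights[, j] *
          (if (cap > 0) cap / peak else 0)
    }
  }
  structure(p, class = "lassonet_params")
}

#' Forward pass of the LassoNet-RNN
#'
#' `h_0 = 0`; `h_t = ReLU(W_in x_t + W_rec h_{t-1} + b_h)` for `t = 1..Q`;
#' the logit is `w_out' h_Q + b_out + b_skip + sum_j theta_j * xbar_j`, where
#' `xbar_j` is the time-mean of variable `j` (the skip connection carries one
#' penalized coefficient per variable).
#'
#' @param params a `lassonet_params` object.
#' @param x a single `Q x M` matrix, or an `(N, Q, M)` array /
#'   `time_series_dataset` for a batch.
#' @return logit(s); apply `plogis()` for probabilities.
#' @export
rnn_forward <- function(params, x) {
  if (inherits(x, "time_series_dataset")) x <- x$values
  single <- is.matrix(x)
  if (single) x <- array(x, dim = c(1, nrow(x), ncol(x)))
  if (length(dim(x)) != 3L) stop("x must be a Q x M matrix or (N, Q, M) array")
  if (dim(x)[3] != length(params$theta))
    stop("x has ", dim(x)[3], " variables but params expect ",
         length(params$theta))
  if (!all(is.finite(x))) stop("x must be finite")
  out <- forward_cpp(params, as_model_cube(x))
  if (single) out[[1]] else as.numeric(out)
}

#' Smooth part of the training objective
#'
#' Mean binary cross-entropy of `plogis(logit)` against the labels (the
#' `lambda * ||theta||_1` part of the objective is handled exactly by the
#' proximal step, not by gradients). With `positive_weight != 1` the mean is
#' weighted.
#'
#' @param params a `lassonet_params` object.
#' @param x `(N, Q, M)` array or `time_series_dataset`.
#' @param y 0/1 labels (taken from `x` when it is a labeled dataset).
#' @param positive_weight relative weight of positive samples.
#' @return the scalar loss.
#' @export
smooth_loss <- function(params, x, y = NULL, positive_weight = 1) {
  if (inherits(x, "time_series_dataset")) {
    if (is.null(y)) y <- x$labels
    x <- x$values
  }
  if (is.null(y) || !length(y)) stop("empty batch: labels are required")
  if (!all(y %in% 0:1)) stop("labels must be 0/1")
  if (dim(x)[1] != length(y)) stop("batch size mismatch between x and y")
  loss_grad_cpp(params, as_model_cube(x), as.numeric(y), positive_weight)$loss
}

#' Gradient of the smooth loss
#'
#' Backprop-through-time gradient of [smooth_loss()] with respect to every
#' parameter, in the same named layout as the parameters.
#'
#' @inheritParams smooth_loss
#' @return `list(loss = ..., grad = lassonet_params-shaped list)`.
#' @export
smooth_loss_grad <- function(params, x, y = NULL, positive_weight = 1) {
  if (inherits(x, "time_series_dataset")) {
    if (is.null(y)) y <- x$labels
    x <- x$values
  }
  if (is.null(y) || !length(y)) stop("empty batch: labels are required")
  loss_grad_cpp(params, as_model_cube(x), as.numeric(y), positive_weight)
}

#' One Adam update step
#'
#' Standard Adam (`beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8`) on the smooth
#' loss over the given batch. Does not apply the proximal operator; compose
#' with [prox_all()] for proximal-gradient training.
#'
#' @inheritParams smooth_loss
#' @param hyper a [lassonet_hyper()] (only `learning_rate` and
#'   `positive_weight` are used here).
#' @param state optimizer state from a previous call, or `NULL` to start.
#' @return `list(params, state, loss)`.
#' @export
adam_step <- function(params, x, y = NULL, hyper = lassonet_hyper(),
                      state = NULL) {
  if (inherits(x, "time_series_dataset")) {
    if (is.null(y)) y <- x$labels
    x <- x$values
  }
  if (is.null(y) || !length(y)) stop("empty batch: labels are required")
  res <- adam_step_cpp(params, if (is.null(state)) list() else state,
                       as_model_cube(x), as.numeric(y),
                       hyper$learning_rate, hyper$positive_weight)
  res$params <- normalize_params(res$params)
  res
}

#' Save / load a parameter checkpoint
#'
#' Flat JSON archive of the named parameter arrays (full double precision)
#' with the hyperparameters as a sidecar field.
#'
#' @param params a `lassonet_params` object.
#' @param hyper the [lassonet_hyper()] used to train it (stored alongside).
#' @param path output `.json` file.
#' @return `path` invisibly (`save_checkpoint`); `list(params, hyper)`
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(params, hyper, path) {
  payload <- list(
    format = "lassonetrnn-checkpoint-v1",
    hyper = unclass(hyper),
    dims = list(H = nrow(params$input_weights),
                M = ncol(params$input_weights)),
    params = lapply(unclass(params), function(x) as.numeric(x)))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "lassonetrnn-checkpoint-v1"))
    stop("not a lassonetrnn checkpoint: ", path)
  H <- payload$dims$H; M <- payload$dims$M
  p <- payload$params
  params <- structure(list(
    theta = as.numeric(p$theta),
    input_weights = matrix(p$input_weights, H, M),
    recurrent_weights = matrix(p$recurrent_weights, H, H),
    hidden_bias = as.numeric(p$hidden_bias),
    output_weights = as.numeric(p$output_weights),
    output_bias = as.numeric(p$output_bias),
    skip_bias = as.numeric(p$skip_bias)), class = "lassonet_params")
  hy <- payload$hyper
  hyper <- lassonet_hyper(
    hidden_size = hy$hidden_size,
    hierarchy_multiplier = if (is.character(hy$hierarchy_multiplier))
      Inf else hy$hierarchy_multiplier,
    lambda_start = hy$lambda_start, path_multiplier = hy$path_multiplier,
    epochs_per_lambda = hy$epochs_per_lambda, dense_epochs = hy$dense_epochs,
    learning_rate = hy$learning_rate, batch_size = hy$batch_size,
    seed = hy$seed, patience = hy$patience, prox_mode = hy$prox_mode,
    positive_weight = hy$positive_weight)
  list(params = params, hyper = hyper)
}
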