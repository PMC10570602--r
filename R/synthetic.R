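#' Specification of a synthetic survey panel
#'
#' Describes a 3-wave-style panel of mixed binary / ordinal / continuous
#' variables with a binary outcome driven partly by static linear effects of
#' the per-subject time-mean of some features and partly by purely temporal
#' effects (first-to-last wave change) of others, plus completely-at-random
#' cell missingness. The defaults are the package's standard recovery test
#' bed: 600 subjects, 3 waves, 20 features, two static and one temporal
#' planted effect of size 1, noise sd 0.5, 10% missing cells.
#'
#' @param n_subjects,n_waves,n_features panel dimensions.
#' @param static_relevant indices of features with a static (time-mean)
#'   effect on the outcome.
#' @param temporal_relevant indices of features whose first-to-last wave
#'   change drives the outcome; disjoint from `static_relevant`.
#' @param static_effects,temporal_effects effect sizes, one per planted
#'   feature.
#' @param noise_sd sd of the Gaussian noise added to the linear predictor.
#' @param missing_rate probability that any one cell is unobserved.
#' @param intercept intercept of the linear predictor; the default -1 gives
#'   roughly 30% positive prevalence under the default effects, matching the
#'   imbalance regime of depression panels.
#' @param feature_kinds character vector (`"continuous"`, `"binary"`,
#'   `"ordinal"`) per feature; default cycles through the three kinds.
#' @param ordinal_levels number of levels of ordinal features (coded
#'   `0..levels-1`).
#' @param ar_rho wave-to-wave autocorrelation of the latent Gaussian process
#'   behind continuous and ordinal features.
#' @param binary_flip probability that a binary feature flips between
#'   consecutive waves.
#' @param seed integer seed; generation is fully deterministic in it.
#' @return a validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_subjects = 600L, n_waves = 3L, n_features = 20L,
                           static_relevant = c(1L, 4L),
                           temporal_relevant = 7L,
                           static_effects = rep(1, length(static_relevant)),
                           temporal_effects = rep(1, length(temporal_relevant)),
                           noise_sd = 0.5, missing_rate = 0.1,
                           intercept = -1,
                           feature_kinds = NULL, ordinal_levels = 5L,
                           ar_rho = 0.7, binary_flip = 0.2, seed = 1L) {
  if (is.null(feature_kinds))
    feature_kinds <- rep(c("continuous", "binary", "ordinal"),
                         length.out = n_features)
  stopifnot(n_subjects >= 1, n_waves >= 1, n_features >= 1,
            length(feature_kinds) == n_features,
            all(feature_kinds %in% c("continuous", "binary", "ordinal")),
            noise_sd >= 0, missing_rate >= 0, missing_rate < 1,
            length(static_effects) == length(static_relevant),
            length(temporal_effects) == length(temporal_relevant),
            all(is.finite(static_effects)), all(is.finite(temporal_effects)))
  if (length(intersect(static_relevant, temporal_relevant)))
    stop("static and temporal relevant sets must be disjoint")
  if (length(c(static_relevant, temporal_relevant)) &&
      any(c(static_relevant, temporal_relevant) > n_features))
    stop("relevant feature index out of range")
  if (length(temporal_relevant) && n_waves < 2)
    stop("temporal effects need at least 2 waves")
  structure(list(
    n_subjects = as.integer(n_subjects), n_waves = as.integer(n_waves),
    n_features = as.integer(n_features),
    static_relevant = as.integer(static_relevant),
    temporal_relevant = as.integer(temporal_relevant),
    static_effects = as.numeric(static_effects),
    temporal_effects = as.numeric(temporal_effects),
    noise_sd = noise_sd, missing_rate = missing_rate, intercept = intercept,
    feature_kinds = feature_kinds, ordinal_levels = as.integer(ordinal_levels),
    ar_rho = ar_rho, binary_flip = binary_flip, seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Generate a synthetic labeled panel
#'
#' Continuous features follow a stationary AR(1) with standard normal
#' marginals; ordinal features discretize the same latent process into
#' equiprobable levels; binary features persist between waves with
#' probability `1 - binary_flip`. The outcome is
#' `y ~ Bernoulli(plogis(eta))` with
#' `eta = intercept + sum_static beta_j * mean_t(x) +
#' sum_temporal gamma_j * (x_Q - x_1) + Normal(0, noise_sd)`, computed on the
#' complete data before cells are masked out at `missing_rate`.
#'
#' @param spec a [synthetic_spec()].
#' @return `list(dataset = time_series_dataset, truth = sorted indices of
#'   all planted features)`.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  N <- spec$n_subjects; Q <- spec$n_waves; M <- spec$n_features
  with_local_seed(spec$seed, {
    values <- array(NA_real_, dim = c(N, Q, M))
    for (m in seq_len(M)) {
      kind <- spec$feature_kinds[m]
      if (kind == "binary") {
        x <- matrix(0, N, Q)
        x[, 1] <- stats::rbinom(N, 1, 0.5)
        if (Q >= 2) for (q in 2:Q) {
          flip <- stats::rbinom(N, 1, spec$binary_flip) == 1
          x[, q] <- ifelse(flip, 1 - x[, q - 1], x[, q - 1])
        }
        values[, , m] <- x
      } else {
        z <- matrix(0, N, Q)
        z[, 1] <- stats::rnorm(N)
        if (Q >= 2) for (q in 2:Q)
          z[, q] <- spec$ar_rho * z[, q - 1] +
            sqrt(1 - spec$ar_rho^2) * stats::rnorm(N)
        if (kind == "continuous") {
          values[, , m] <- z
        } else {
          L <- spec$ordinal_levels
          breaks <- stats::qnorm(seq_len(L - 1) / L)
          values[, , m] <- matrix(
            findInterval(z, breaks), N, Q)  # levels 0..L-1
        }
      }
    }
    eta <- rep(spec$intercept, N)
    for (k in seq_along(spec$static_relevant)) {
      j <- spec$static_relevant[k]
      eta <- eta + spec$static_effects[k] * rowMeans(values[, , j, drop = FALSE])
    }
    for (k in seq_along(spec$temporal_relevant)) {
      j <- spec$temporal_relevant[k]
      eta <- eta + spec$temporal_effects[k] * (values[, Q, j] - values[, 1, j])
    }
    if (spec$noise_sd > 0) eta <- eta + stats::rnorm(N, 0, spec$noise_sd)
    labels <- stats::rbinom(N, 1, stats::plogis(eta))

    mask <- array(stats::runif(N * Q * M) >= spec$missing_rate,
                  dim = c(N, Q, M))
    values[!mask] <- NA_real_
    ds <- time_series_dataset(values, mask = mask, labels = as.integer(labels))
    list(dataset = ds,
         truth = sort(c(spec$static_relevant, spec$temporal_relevant)))
  })
}

#' Rank-based recovery score of planted features
#'
#' AUC of the exit lambdas as a classifier of planted-feature membership:
#' 1 means every planted feature outranks every noise feature; a random
#' ranking scores 0.5 in expectation. Ties count one half.
#'
#' @param ranking an `importance_ranking` from [feature_importance()].
#' @param truth non-empty integer vector of planted feature indices.
#' @return score in `[0, 1]`.
#' @export
recovery_score <- function(ranking, truth) {
  M <- length(ranking$exit_lambda)
  if (!length(truth)) stop("`truth` must be non-empty")
  if (any(truth < 1 | truth > M)) stop("`truth` indices out of range")
  if (length(truth) >= M) stop("`truth` must be a proper subset of features")
  membership <- as.integer(seq_len(M) %in% truth)
  auc(membership, unname(ranking$exit_lambda))
}
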