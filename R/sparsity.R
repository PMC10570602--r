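#' Soft-thresholding operator
#'
#' `sign(x) * max(|x| - threshold, 0)`, the proximal operator of
#' `threshold * |x|`.
#'
#' @param x numeric vector.
#' @param threshold non-negative threshold.
#' @return thresholded vector.
#' @export
soft_threshold <- function(x, threshold) {
  if (any(threshold < 0)) stop("threshold must be >= 0")
  sign(x) * pmax(abs(x) - threshold, 0)
}

#' Hierarchical proximal operator for one feature
#'
#' Exact global minimizer of
#' \deqn{\tfrac12 (\theta - v)^2 + \tfrac12 \|w - u\|^2 + \lambda_{step}
#'   |\theta| \quad \text{s.t.} \quad \|w\|_\infty \le M_{hier} |\theta|}
#' over `(theta, w)`, given the post-gradient pair `(v, u)`. This is the
#' coupling that lets a variable's network weights survive only while its
#' skip coefficient is nonzero. `M_hier = 0` returns
#' `(soft_threshold(v), 0)`; `M_hier = Inf` returns the unconstrained pair
#' `(soft_threshold(v), u)`. When the minimizer sits exactly at the kink the
#' sparser solution `(0, 0)` is returned.
#'
#' @param theta_j scalar skip coefficient after the gradient step.
#' @param u_j numeric vector (the feature's input-weight column) after the
#'   gradient step.
#' @param lambda_step penalty-times-stepsize threshold, `>= 0`.
#' @param m_hier hierarchy multiplier, `>= 0` or `Inf`.
#' @return `list(theta = scalar, u = vector)`.
#' @export
hier_prox <- function(theta_j, u_j, lambda_step, m_hier) {
  stopifnot(length(theta_j) == 1L, lambda_step >= 0)
  if (is.na(m_hier) || m_hier < 0)
    stop("m_hier must be >= 0 (possibly Inf)")
  res <- hier_prox_cpp(theta_j, matrix(u_j, ncol = 1), lambda_step, m_hier)
  list(theta = as.numeric(res$theta), u = as.numeric(res$input_weights))
}

#' Apply the hierarchical prox to every feature of a parameter set
#'
#' Applies [hier_prox()] independently to each pair (skip coefficient,
#' input-weight column); all other parameters are untouched. The feasibility
#' invariant `||W_j||_inf <= m_hier * |theta_j|` holds exactly afterwards.
#'
#' @param params a `lassonet_params` object.
#' @param lambda penalty level, `>= 0`.
#' @param lr learning rate (the threshold is `lambda * lr`).
#' @param m_hier hierarchy multiplier.
#' @return the proxed `lassonet_params`.
#' @export
prox_all <- function(params, lambda, lr, m_hier) {
  stopifnot(lambda >= 0, lr > 0)
  M <- length(params$theta)
  res <- hier_prox_cpp(params$theta, params$input_weights,
                       rep(lambda * lr, M), m_hier)
  params$theta <- as.numeric(res$theta)
  params$input_weights <- res$input_weights
  params
}

#' Active feature set
#'
#' Indices of features whose skip coefficient exceeds `tolerance` in
#' magnitude. With the default tolerance 0 this is exact-zero screening: the
#' proximal operator produces exact zeros, so no numerical fudge is needed.
#'
#' @param params a `lassonet_params` object.
#' @param tolerance non-negative threshold, default 0.
#' @return integer vector of 1-based feature indices.
#' @export
active_set <- function(params, tolerance = 0) {
  stopifnot(tolerance >= 0)
  which(abs(params$theta) > tolerance)
}
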