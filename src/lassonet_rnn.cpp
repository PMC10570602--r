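// Core numerics for the LassoNet-RNN model: batched forward pass of a
// single-layer ReLU RNN with a per-variable linear skip connection,
// backprop-through-time gradients of the binary cross-entropy loss, the Adam
// optimizer, and the closed-form hierarchical proximal operator that enforces
// ||W_j||_inf <= M_hier * |theta_j| together with the lambda*|theta_j|
// penalty after every gradient step.
//
// Data layout: X is an arma::cube of shape (N, M, Q) — slice t is the N x M
// matrix of wave t (the R side permutes from its native (N, Q, M) array).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::as;

static inline double soft_thr(double x, double l) {
  if (x > l) return x - l;
  if (x < -l) return x + l;
  return 0.0;
}

struct Net {
  vec theta;   // M skip coefficients
  mat Win;     // H x M, column j is the hierarchically constrained W_j
  mat Wrec;    // H x H
  vec bh;      // H
  vec wout;    // H
  double bout;
  double bskip;
};

static Net net_from_list(const List& p) {
  Net n;
  n.theta = as<vec>(p["theta"]);
  n.Win = as<mat>(p["input_weights"]);
  n.Wrec = as<mat>(p["recurrent_weights"]);
  n.bh = as<vec>(p["hidden_bias"]);
  n.wout = as<vec>(p["output_weights"]);
  n.bout = as<double>(p["output_bias"]);
  n.bskip = as<double>(p["skip_bias"]);
  return n;
}

static List net_to_list(const Net& n) {
  return List::create(
    Named("theta") = n.theta,
    Named("input_weights") = n.Win,
    Named("recurrent_weights") = n.Wrec,
    Named("hidden_bias") = n.bh,
    Named("output_weights") = n.wout,
    Named("output_bias") = n.bout,
    Named("skip_bias") = n.bskip);
}

// ---------------------------------------------------------------------------
// Forward pass

static vec forward_logits(const Net& n, const cube& X) {
  const uword N = X.n_rows, Q = X.n_slices;
  const uword H = n.Win.n_rows;
  mat h(N, H, fill::zeros);
  for (uword t = 0; t < Q; ++t) {
    mat A = X.slice(t) * n.Win.t() + h * n.Wrec.t();
    A.each_row() += n.bh.t();
    h = clamp(A, 0.0, datum::inf);
  }
  mat xbar = mean(X, 2);  // N x M time-mean of each variable
  vec logit = h * n.wout + xbar * n.theta;
  logit += n.bout + n.bskip;
  return logit;
}

// numerically stable mean weighted BCE: sum_i w_i * (softplus(z_i) - y_i z_i)
static double bce_from_logits(const vec& logit, const vec& y, const vec& w) {
  double loss = 0.0;
  for (uword i = 0; i < logit.n_elem; ++i) {
    double z = logit(i);
    double sp = (z > 0) ? z + std::log1p(std::exp(-z)) : std::log1p(std::exp(z));
    loss += w(i) * (sp - y(i) * z);
  }
  return loss;
}

// ---------------------------------------------------------------------------
// Loss + gradient (BPTT)

static double loss_and_grad(const Net& n, const cube& X, const vec& y,
                            const vec& w, Net& g) {
  const uword N = X.n_rows, Q = X.n_slices;
  const uword H = n.Win.n_rows, M = n.Win.n_cols;

  std::vector<mat> hs(Q + 1);  // hs[t] = hidden state after t steps
  hs[0] = mat(N, H, fill::zeros);
  for (uword t = 0; t < Q; ++t) {
    mat A = X.slice(t) * n.Win.t() + hs[t] * n.Wrec.t();
    A.each_row() += n.bh.t();
    hs[t + 1] = clamp(A, 0.0, datum::inf);
  }
  mat xbar = mean(X, 2);
  vec logit = hs[Q] * n.wout + xbar * n.theta;
  logit += n.bout + n.bskip;
  double loss = bce_from_logits(logit, y, w);

  vec p = 1.0 / (1.0 + exp(-logit));
  vec dl = w % (p - y);  // dLoss/dlogit

  g.wout = hs[Q].t() * dl;
  g.bout = accu(dl);
  g.bskip = g.bout;
  g.theta = xbar.t() * dl;
  g.Win = mat(H, M, fill::zeros);
  g.Wrec = mat(H, H, fill::zeros);
  g.bh = vec(H, fill::zeros);

  mat dh = dl * n.wout.t();  // N x H
  for (uword t = Q; t >= 1; --t) {
    mat dA = dh % conv_to<mat>::from(hs[t] > 0);  // ReLU mask
    g.Win += dA.t() * X.slice(t - 1);
    g.Wrec += dA.t() * hs[t - 1];
    g.bh += sum(dA, 0).t();
    if (t > 1) dh = dA * n.Wrec;
  }
  return loss;
}

// ---------------------------------------------------------------------------
// Hierarchical proximal operator (single feature)
//
// Exact minimizer of 1/2 (b - v)^2 + 1/2 ||wv - u||^2 + lam * |b|
// subject to ||wv||_inf <= Mh * |b|.

static void hier_prox_one(double v, const vec& u, double lam, double Mh,
                          double& theta_out, vec& u_out) {
  const uword K = u.n_elem;
  if (!std::isfinite(Mh)) {  // constraint never binds
    theta_out = soft_thr(v, lam);
    u_out = u;
    return;
  }
  if (Mh == 0.0) {  // pure lasso branch: network column forced to zero
    theta_out = soft_thr(v, lam);
    u_out = vec(K, fill::zeros);
    return;
  }
  vec au = sort(abs(u), "descend");
  double s = 0.0, w_sel = 0.0;
  for (uword m = 0; m <= K; ++m) {
    if (m > 0) s += au(m - 1);
    double w = Mh / (1.0 + double(m) * Mh * Mh) *
               soft_thr(std::abs(v) + Mh * s, lam);
    double hi = (m == 0) ? datum::inf : au(m - 1);
    double lo = (m == K) ? 0.0 : au(m);
    if (w <= hi && w >= lo) { w_sel = w; break; }
  }
  if (w_sel <= 0.0) {  // kink tie-break: prefer the sparse solution
    theta_out = 0.0;
    u_out = vec(K, fill::zeros);
    return;
  }
  double sgn = (v > 0) - (v < 0);
  if (sgn == 0.0) sgn = 1.0;
  theta_out = sgn * w_sel / Mh;
  u_out = sign(u) % min(abs(u), vec(K, fill::value(w_sel)));
}

// [[Rcpp::export]]
List hier_prox_cpp(const arma::vec& theta, const arma::mat& input_weights,
                   const arma::vec& lambda_steps, double m_hier) {
  const uword M = theta.n_elem;
  vec theta_out(M);
  mat U_out(input_weights.n_rows, M);
  vec ucol;
  for (uword j = 0; j < M; ++j) {
    double th;
    hier_prox_one(theta(j), input_weights.col(j), lambda_steps(j), m_hier,
                  th, ucol);
    theta_out(j) = th;
    U_out.col(j) = ucol;
  }
  return List::create(Named("theta") = theta_out,
                      Named("input_weights") = U_out);
}

// ---------------------------------------------------------------------------
// Adam

struct AdamState {
  Net m, v;
  long t;
};

static Net net_zeros(uword H, uword M) {
  Net z;
  z.theta = vec(M, fill::zeros);
  z.Win = mat(H, M, fill::zeros);
  z.Wrec = mat(H, H, fill::zeros);
  z.bh = vec(H, fill::zeros);
  z.wout = vec(H, fill::zeros);
  z.bout = 0.0;
  z.bskip = 0.0;
  return z;
}

static AdamState state_from_list(const List& s, uword H, uword M) {
  AdamState st;
  if (s.size() == 0) {
    st.m = net_zeros(H, M);
    st.v = net_zeros(H, M);
    st.t = 0;
  } else {
    st.m = net_from_list(s["m"]);
    st.v = net_from_list(s["v"]);
    st.t = as<long>(s["t"]);
  }
  return st;
}

static List state_to_list(const AdamState& st) {
  return List::create(Named("m") = net_to_list(st.m),
                      Named("v") = net_to_list(st.v),
                      Named("t") = double(st.t));
}

static const double B1 = 0.9, B2 = 0.999, EPS = 1e-8;

static inline void adam_mat(mat& x, mat& m, mat& v, const mat& g,
                            double lr, double c1, double c2) {
  m = B1 * m + (1 - B1) * g;
  v = B2 * v + (1 - B2) * square(g);
  x -= lr * (m / c1) / (sqrt(v / c2) + EPS);
}
static inline void adam_vec(vec& x, vec& m, vec& v, const vec& g,
                            double lr, double c1, double c2) {
  m = B1 * m + (1 - B1) * g;
  v = B2 * v + (1 - B2) * square(g);
  x -= lr * (m / c1) / (sqrt(v / c2) + EPS);
}
static inline void adam_sca(double& x, double& m, double& v, double g,
                            double lr, double c1, double c2) {
  m = B1 * m + (1 - B1) * g;
  v = B2 * v + (1 - B2) * g * g;
  x -= lr * (m / c1) / (std::sqrt(v / c2) + EPS);
}

static void adam_update(Net& n, AdamState& st, const Net& g, double lr) {
  st.t += 1;
  double c1 = 1.0 - std::pow(B1, double(st.t));
  double c2 = 1.0 - std::pow(B2, double(st.t));
  adam_vec(n.theta, st.m.theta, st.v.theta, g.theta, lr, c1, c2);
  adam_mat(n.Win, st.m.Win, st.v.Win, g.Win, lr, c1, c2);
  adam_mat(n.Wrec, st.m.Wrec, st.v.Wrec, g.Wrec, lr, c1, c2);
  adam_vec(n.bh, st.m.bh, st.v.bh, g.bh, lr, c1, c2);
  adam_vec(n.wout, st.m.wout, st.v.wout, g.wout, lr, c1, c2);
  adam_sca(n.bout, st.m.bout, st.v.bout, g.bout, lr, c1, c2);
  adam_sca(n.bskip, st.m.bskip, st.v.bskip, g.bskip, lr, c1, c2);
}

// Per-feature proximal thresholds. In the "adam_metric" mode the l1 threshold
// is taken in the same diagonal metric Adam uses for its step, which restores
// the exact l1 stationarity conditions (see methods vignette); in "lr" mode
// the classical lambda*lr is used.
static vec prox_thresholds(double lambda, double lr, const AdamState& st,
                           bool adam_metric) {
  const uword M = st.v.theta.n_elem;
  if (!adam_metric || st.t == 0)
    return vec(M, fill::value(lambda * lr));
  double c2 = 1.0 - std::pow(B2, double(st.t));
  vec vhat = st.v.theta / c2;
  return lambda * lr / (sqrt(vhat) + EPS);
}

static void apply_prox(Net& n, double lambda, double lr, const AdamState& st,
                       double m_hier, bool adam_metric) {
  vec thr = prox_thresholds(lambda, lr, st, adam_metric);
  vec ucol;
  for (uword j = 0; j < n.theta.n_elem; ++j) {
    double th;
    hier_prox_one(n.theta(j), n.Win.col(j), thr(j), m_hier, th, ucol);
    n.theta(j) = th;
    n.Win.col(j) = ucol;
  }
}

// ---------------------------------------------------------------------------
// Training loop: epochs of minibatch Adam (+ prox), early stopping on the
// full-sample penalized training objective.

static cube subset_cube(const cube& X, const uvec& idx) {
  cube out(idx.n_elem, X.n_cols, X.n_slices);
  for (uword t = 0; t < X.n_slices; ++t) out.slice(t) = X.slice(t).rows(idx);
  return out;
}

static vec sample_weights(const vec& y, double pos_weight) {
  vec w(y.n_elem);
  for (uword i = 0; i < y.n_elem; ++i) w(i) = (y(i) == 1.0) ? pos_weight : 1.0;
  return w / accu(w);
}

// [[Rcpp::export]]
List train_cpp(List params_, List state_, const arma::cube& X,
               const arma::vec& y, double lambda, double lr, int epochs,
               int batch_size, double m_hier, int patience, bool apply_prox_,
               bool adam_metric, double pos_weight, int seed) {
  Net n = net_from_list(params_);
  const uword N = X.n_rows, H = n.Win.n_rows, M = n.Win.n_cols;
  AdamState st = state_from_list(state_, H, M);
  Net g = net_zeros(H, M);

  std::mt19937 rng(static_cast<unsigned>(seed));
  vec w_full = sample_weights(y, pos_weight);

  double best = datum::inf;
  int wait = 0, epochs_run = 0;
  uvec perm = regspace<uvec>(0, N - 1);
  const uword B = std::min<uword>(batch_size, N);

  for (int e = 0; e < epochs; ++e) {
    // Fisher-Yates with the local RNG (deterministic across platforms)
    for (uword i = N - 1; i > 0; --i) {
      std::uniform_int_distribution<uword> d(0, i);
      std::swap(perm(i), perm(d(rng)));
    }
    for (uword start = 0; start < N; start += B) {
      uword stop = std::min(start + B - 1, N - 1);
      uvec idx = perm.subvec(start, stop);
      cube Xb = subset_cube(X, idx);
      vec yb = y.elem(idx);
      vec wb = sample_weights(yb, pos_weight);
      loss_and_grad(n, Xb, yb, wb, g);
      adam_update(n, st, g, lr);
      if (apply_prox_) apply_prox(n, lambda, lr, st, m_hier, adam_metric);
    }
    ++epochs_run;
    double obj = bce_from_logits(forward_logits(n, X), y, w_full) +
                 lambda * accu(abs(n.theta));
    if (obj < best - 1e-10) {
      best = obj;
      wait = 0;
    } else if (++wait > patience) {
      break;
    }
  }
  return List::create(Named("params") = net_to_list(n),
                      Named("state") = state_to_list(st),
                      Named("epochs_run") = epochs_run,
                      Named("objective") = best);
}

// [[Rcpp::export]]
arma::vec forward_cpp(List params_, const arma::cube& X) {
  return forward_logits(net_from_list(params_), X);
}

// [[Rcpp::export]]
List loss_grad_cpp(List params_, const arma::cube& X, const arma::vec& y,
                   double pos_weight) {
  Net n = net_from_list(params_);
  Net g = net_zeros(n.Win.n_rows, n.Win.n_cols);
  vec w = sample_weights(y, pos_weight);
  double loss = loss_and_grad(n, X, y, w, g);
  return List::create(Named("loss") = loss, Named("grad") = net_to_list(g));
}

// [[Rcpp::export]]
List adam_step_cpp(List params_, List state_, const arma::cube& X,
                   const arma::vec& y, double lr, double pos_weight) {
  Net n = net_from_list(params_);
  AdamState st = state_from_list(state_, n.Win.n_rows, n.Win.n_cols);
  Net g = net_zeros(n.Win.n_rows, n.Win.n_cols);
  vec w = sample_weights(y, pos_weight);
  double loss = loss_and_grad(n, X, y, w, g);
  adam_update(n, st, g, lr);
  return List::create(Named("params") = net_to_list(n),
                      Named("state") = state_to_list(st),
                      Named("loss") = loss);
}
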