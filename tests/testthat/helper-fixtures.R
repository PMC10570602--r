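# Shared fixtures, all generated in code.

# small complete labeled panel with reproducible values
make_panel <- function(N = 8, Q = 3, M = 4, seed = 1, labels = TRUE) {
  set.seed(seed)
  values <- array(rnorm(N * Q * M), dim = c(N, Q, M))
  time_series_dataset(
    values,
    labels = if (labels) rep_len(c(0L, 1L), N),
    feature_names = paste0("f", seq_len(M)),
    time_labels = seq_len(Q))
}

# long CSV on disk for the readers; returns the path
write_long_fixture <- function(df, dir = withr::local_tempdir(.local_envir =
                                 parent.frame())) {
  path <- file.path(dir, "panel.csv")
  data.table::fwrite(df, path, na = "NA")
  path
}

# independently coded brute-force CESD-10 scorer: per-item lookup tables
# written out explicitly, no arithmetic shared with score_cesd()
brute_cesd <- function(resp) {
  neg <- c(0L, 1L, 2L, 3L)   # options 1..4 for the 8 negative items
  pos <- c(3L, 2L, 1L, 0L)   # options 1..4 for items 5 and 8
  total <- 0L
  for (i in 1:10)
    total <- total + if (i %in% c(5L, 8L)) pos[resp[i]] else neg[resp[i]]
  total
}

# brute-force oracle for the hierarchical prox: dense 1-d grid over theta
# (w eliminated by exact per-coordinate clipping), refined near the optimum
brute_hier_prox_value <- function(v, u, lam, Mh) {
  f <- function(th) {
    w <- pmin(pmax(u, -Mh * abs(th)), Mh * abs(th))
    0.5 * (th - v)^2 + 0.5 * sum((w - u)^2) + lam * abs(th)
  }
  span <- max(3, abs(v) + 1)
  g <- seq(-span, span, length.out = 4001)
  b <- g[which.min(vapply(g, f, 0))]
  step <- g[2] - g[1]
  for (r in 1:6) {
    g <- seq(b - 2 * step, b + 2 * step, length.out = 401)
    b <- g[which.min(vapply(g, f, 0))]
    step <- g[2] - g[1]
  }
  f(b)
}

hier_objective <- function(theta, u_out, v, u, lam) {
  0.5 * (theta - v)^2 + 0.5 * sum((u_out - u)^2) + lam * abs(theta)
}

# toy replicated-wave dataset whose time-means equal a plain design matrix;
# used for the lasso-equivalence checks
make_lasso_toy <- function(N = 800, seed = 99) {
  set.seed(seed)
  X <- matrix(rnorm(N * 6), N, 6)
  beta <- c(2, -2, 1.5, 0, 0, 0)
  y <- rbinom(N, 1, plogis(drop(X %*% beta)))
  values <- array(0, dim = c(N, 3, 6))
  for (q in 1:3) values[, q, ] <- X
  list(ds = time_series_dataset(values, labels = as.integer(y)),
       X = X, y = y)
}

zero_params_like <- function(H, M) {
  structure(list(theta = numeric(M), input_weights = matrix(0, H, M),
                 recurrent_weights = matrix(0, H, H), hidden_bias = numeric(H),
                 output_weights = numeric(H), output_bias = 0, skip_bias = 0),
            class = "lassonet_params")
}

fast_hyper <- function(...) {
  defaults <- list(hidden_size = 4L, dense_epochs = 30L,
                   epochs_per_lambda = 30L, path_multiplier = 1.3,
                   batch_size = 32L)
  do.call(lassonet_hyper, utils::modifyList(defaults, list(...)))
}
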