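# lassonetrnn

Sparse feature selection for **multivariate time-series classification**,
aimed at longitudinal survey panels: which of the variables measured at every
wave actually drive a binary outcome such as late-life depression, and in
what order of importance?

The package implements a LassoNet-style architecture in which each variable
`j` owns a linear **skip connection** `theta_j` (applied to the variable's
time-mean) alongside a single-layer ReLU **recurrent network** that sees the
full wave-by-wave sequence. The two are tied by a hierarchical constraint, so
a variable can feed the network only while its linear coefficient is alive:

```
minimize_{theta, W}  L(theta, W) + lambda * ||theta||_1
subject to           ||W_j^(1)||_inf  <=  M * |theta_j|,   j = 1..d
```

`L` is the binary cross-entropy of the network-plus-skip logit, `W_j^(1)` is
column `j` of the (time-shared) input-to-hidden matrix, and `M` is the
hierarchy multiplier: `M = 0` collapses the model to an l1-penalized
(lasso) logistic regression on time-mean features; `M = +Inf` leaves an
unconstrained RNN with a soft-thresholded skip. Optimization is
proximal-gradient: each Adam step is followed by the exact closed-form
**hierarchical proximal operator**, so screening produces exact zeros.

Training walks a dense-to-sparse **regularization path** over a geometric
lambda sequence until every skip coefficient is zero. The largest lambda at
which a variable is still active — its *exit lambda* — is its importance;
sorting exit lambdas descending (ties share a rank) gives the per-variable
importance ranking.

Around the model the package provides the survey plumbing: long/wide CSV and
sktime-style `.ts` readers, mean/carry-forward imputation, z-score
normalization, stratified train/test splitting, CESD-10 depression-scale
scoring with the `> 10` case threshold, accuracy/F1/AUC metrics, Pearson
chi-square association tests, and a synthetic 3-wave panel generator with
planted static and temporal effects for recovery benchmarking.

## Worked example

Generate a 600-subject, 3-wave, 20-variable panel in which variables 1 and 4
act through their level and variable 7 acts *only* through its wave-to-wave
change, fit the path, and rank:

```r
library(lassonetrnn)

gen  <- generate_panel(synthetic_spec(seed = 1))
gen$truth
#> [1] 1 4 7
pp   <- preprocess_and_split(gen$dataset, train_fraction = 0.8, seed = 1)
path <- fit_path(pp$train, pp$test, lassonet_hyper(seed = 1))
path
#> lassonet_path: 69 lambda values from 5.243 to 20.15
#>   20 features; terminal active set size 0
rk <- feature_importance(path)
head(as.data.frame(rk), 4)
#>  feature exit_lambda rank
#>       V1   19.759749    1
#>       V4   15.274929    2
#>       V7    8.105386    3
#>       V9    5.242880    4
recovery_score(rk, gen$truth)
#> [1] 1
```

All three planted variables — including the purely temporal V7, which is
invisible to a static lasso on time-means — occupy the top three ranks, and
the ranking separates planted from noise variables perfectly
(`recovery_score` is the AUC of exit lambdas against planted membership).

Scoring a depression scale and testing an association:

```r
score_cesd(c(1,1,1,1,1,1,1,1,1,1))       # reverse-coded items 5 and 8 -> 6
label_depression(11)                     # 1 (case: score > 10)
pearson_chi2(matrix(c(384, 1284, 871, 1348), 2, byrow = TRUE))$statistic
#> [1] 114.7343
```

A command-line front end mirrors the pipeline
(`simulate`, `fit-path`, `rank`, `evaluate`, `chi2`, `score-cesd`):

```sh
Rscript exec/lassonetrnn simulate --seed 1 --out sim/
Rscript exec/lassonetrnn fit-path --input sim/panel.csv --out fit/ --seed 1
Rscript exec/lassonetrnn rank --input fit/path.json --out rank/
```

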