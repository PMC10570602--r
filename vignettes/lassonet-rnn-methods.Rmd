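---
title: "Hierarchical sparse feature selection on survey panels: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical sparse feature selection on survey panels: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lassonetrnn)
```

## The problem

Longitudinal surveys measure the same variables on the same subjects at
several waves. Some variables influence a binary outcome through their
*level* (a static effect, visible in any cross-section), others only through
their *trajectory* — the change between waves. A lasso on per-subject
summaries captures the first kind and is structurally blind to the second;
an unpenalized recurrent network captures both but selects nothing. This
package couples the two so that selection and temporal modeling happen
jointly.

## Model

Each subject is a matrix of `Q` waves by `M` variables. A single-layer ReLU
RNN consumes the sequence:

$$h^{(t)} = \mathrm{ReLU}(W^{(1)} x_t + U h^{(t-1)} + b), \qquad h^{(0)} = 0,$$

and the classification logit is

$$z = w_{out}^\top h^{(Q)} + b_{out} + b_{skip} + \sum_j \theta_j \bar
x_j,$$

with $\bar x_j$ the time-mean of variable $j$. Training minimizes the mean
binary cross-entropy plus $\lambda \lVert\theta\rVert_1$, subject to the
per-variable hierarchy constraint $\lVert W^{(1)}_j \rVert_\infty \le
M_{hier}\,|\theta_j|$. The constraint is the whole point: once the prox
drives $\theta_j$ to exactly zero, column $j$ of $W^{(1)}$ is clipped to
zero too, and variable $j$ is out of the model entirely. Conversely a
variable whose signal lives only in the recurrent part (a temporal effect)
keeps a small nonzero $\theta_j$ alive because the prox trades the clipping
loss of a useful column against the l1 penalty.

**Skip across time.** The penalty indexes one coefficient per *variable*,
not per variable-wave. We therefore apply $\theta_j$ to the time-mean
$\bar x_j$: exactly one penalized coefficient per variable, so the exit
lambda and the importance ranking are defined per variable with no further
aggregation. (A per-lag skip with a group penalty would be the natural
alternative; it is deliberately not implemented — it changes the prox to a
group variant while the acceptance surface of this package only exercises
the per-variable form.)

**Cell and head.** Vanilla RNN (no LSTM/GRU), single layer, $h^{(0)}=0$, no
layer normalization; a single logistic output unit. The `(N, Q, M)` tensor
convention and the time-shared input matrix make the constraint's `K` equal
to the hidden width.

## Optimization

Proximal gradient with Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\varepsilon = 10^{-8}$): after **every** minibatch Adam step, each pair
$(\theta_j, W^{(1)}_j)$ passes through the exact hierarchical proximal
operator — the closed-form global minimizer of

$$\tfrac12(\theta - v)^2 + \tfrac12\lVert w - u\rVert^2 +
\lambda_{step}|\theta| \quad \text{s.t.}\quad \lVert w\rVert_\infty \le
M_{hier}|\theta|,$$

computed by sorting $|u|$ and scanning the `K + 1` candidate clip levels.
The closed form is verified in the test suite against a brute-force
grid-with-refinement oracle (200 random instances, objective gap
$\le 10^{-6}$) before anything downstream trusts it. When the minimizer
lands exactly on the kink the sparser solution $(0, 0)$ is returned.

**Thresholding in the Adam metric.** Plain proximal gradient uses
$\lambda_{step} = \lambda \cdot lr$. Under Adam that rule breaks: near a
stationary point the Adam direction approaches $lr \cdot \mathrm{sign}(g)$,
so a coordinate at zero escapes whenever $\lambda < 1$ and is trapped
whenever $\lambda > 1$ — screening would happen at $\lambda \approx 1$
regardless of the data, and the $M_{hier}=0$ model would *not* solve the
lasso problem. We therefore threshold each $\theta_j$ in the same diagonal
metric Adam uses for its step,
$\lambda_{step,j} = \lambda \cdot lr / (\sqrt{\hat v_j} + \varepsilon)$,
which restores the exact l1 stationarity conditions
($|g_j| \le \lambda$ for inactive, $g_j = -\lambda\,\mathrm{sign}(\theta_j)$
for active coordinates). The test suite confirms that with $M_{hier} = 0$
the fitted coefficients match `glmnet` to two decimal places on a shared
$\lambda$ grid. The classical rule remains available as
`prox_mode = "lr"`. One known distortion: the constraint term
$M_{hier}\sum|u|$ inside the prox is *not* rescaled by $\sqrt{\hat v_j}$,
so for a variable with a vanishing full-batch skip gradient the threshold
can be relatively large; with the default minibatch training, gradient
noise keeps $\hat v_j$ floored and the effect is minor.

## The regularization path

1. **Dense pretraining** — `dense_epochs` of Adam at $\lambda = 0$, no prox
   (the constraint may be violated here; the first prox restores it).
2. **Start calibration** — `lambda_start = "auto"` probes a doubling ladder
   of candidates, one epoch each from a cloned optimizer state, and takes
   the largest candidate screening at most one feature, divided by 10.
3. **Path** — $\lambda_k = \lambda_{start} \cdot m^k$ (default
   `path_multiplier` 1.02), warm-started, up to `epochs_per_lambda` epochs
   with early stopping on the penalized training objective (patience 5,
   improvement tolerance $10^{-10}$), one recorded point per $\lambda$,
   until the active set is empty. A guard errors if
   $\lambda > 10^6 \lambda_{start}$ with features still active.

Features are not frozen after exit; re-entry through warm-started gradients
is possible (rare), and the importance rule — exit lambda = the **largest**
$\lambda$ at which the feature was active, 0 for never-active features —
absorbs it. Ties share a (min) rank, and `select_k_features` expands across
a tie boundary rather than breaking it arbitrarily. Train and test metrics
(accuracy, Mann–Whitney AUC, F1 at threshold 0.5) are recorded at every
point; neither is privileged.

## Defaults and units

| parameter | default | why |
|---|---|---|
| `hidden_size` | 16 | small panels (hundreds of subjects); larger widths overfit before they help |
| `hierarchy_multiplier` | 10 | loose coupling: a variable needs only $|\theta_j| \ge \lVert W_j\rVert_\infty/10$ to keep its column |
| `path_multiplier` | 1.02 | fine geometric grid so exit order is resolved |
| `learning_rate` | 1e-3 | standard Adam scale for standardized inputs |
| `batch_size` | 64 | minibatch noise keeps the Adam-metric thresholds well conditioned (see above) |
| `dense_epochs` / `epochs_per_lambda` | 100 / 100 | warm starts converge in far fewer; patience-5 early stopping does the real budgeting |
| `positive_weight` | 1 | the ~30% class imbalance of depression panels does not need reweighting for ranking; a weight is available |

These are configuration, not claims: the reference analysis this design
follows reports no architecture constants, and every one of them is
inspectable via the CLI's `--show-config`.

## Preprocessing

Mean imputation is the default (the only fully determined choice among the
standard candidates); carry-forward and constant fill are available. A
subject absent from a wave contributes mask-false cells for that whole
wave, which imputation then fills; `filter_subjects` exposes the
remove-invalid-data step as a missingness-fraction row filter (default
keeps all). Normalization is z-score per feature **pooled over waves**
(population sd; constant features get scale 1 and map to 0); min–max is
available. Pooling rather than per-wave normalization is an assumption —
per-wave statistics would erase level shifts between waves, which is
exactly the signal a temporal model should see. The split is stratified by
label with a required seed, protecting the minority class. One ordering
subtlety: the flowchart order "impute, normalize, split" conflicts with
fitting normalization statistics on training data only, so
`preprocess_and_split` imputes globally, splits, then fits the normalizer
on the training split and applies it to both. The leakage through global
feature means is the usual, minor kind; users who care can compose the
steps manually in the stricter order.

## CESD-10 labeling

Items score `option − 1` except the two positively worded items (5 and 8)
which score `4 − option`; totals lie in [0, 30] and scores **strictly
above 10** define a case. Missing items are a hard error — prorating a
10-item scale silently shifts the threshold. The scorer is tested against
an independently coded lookup-table scorer on 1,000 random response sheets
and exhaustively at the bounds.

## Synthetic test bed

`synthetic_spec()` emulates a 3-wave survey panel: ~2/3 of features are
binary (wave-to-wave flip probability 0.2) or ordinal (5 levels from a
discretized latent AR(1)), the rest continuous AR(1) with standard normal
marginals and lag-1 correlation 0.7. The outcome is Bernoulli-logistic in
`intercept + static effects on time-means + temporal effects on
first-to-last-wave change + N(0, noise_sd)` noise, with 10% of cells
missing completely at random. The default plants two static effects and one
temporal effect, all of size 1, on **continuous** carriers — effect sizes
are then interpretable on a standardized scale, and the static/temporal
contrast is clean: for a stationary AR(1), the wave change `x_Q − x_1` is
uncorrelated with the time-mean, so the temporal feature is provably
invisible to the `M_hier = 0` reduction. The intercept −1 gives roughly
30% positive prevalence, the imbalance regime of depression panels.

What a green recovery test establishes: on panels of this kind (MCAR
missingness, independent features, linear-in-link effects), the path ranks
planted variables above noise (mean exit-lambda AUC ≥ 0.9 over 20 seeds)
and specifically recovers the temporal variable where the static reduction
cannot. What it does not establish: behavior under informative missingness,
correlated confounders, survey weights, or effects that are nonlinear in
the link — none of which the generator emulates — nor any claim about the
original restricted-access survey data, whose importance values and
near-perfect accuracies are not reproducible without that data.

## Numerical choices, degeneracies

- Screening is **exact**: the prox writes literal zeros, so `active_set`
  needs no tolerance.
- BCE is computed via the stable softplus form; zero-parameter models give
  exactly `log 2` per sample.
- AUC is the tie-aware rank statistic (ties count one half), not a
  thresholded curve.
- F1 with an all-zero denominator is defined as 0 with a warning; the
  chi-square test refuses tables with a zero marginal.
- Determinism: R-side randomness (init, split, generator) goes through a
  seed-scoped RNG restore; the C++ training loop uses its own
  `std::mt19937` seeded per path stage, so identical seeds give identical
  paths bit-for-bit, independent of the session RNG state.
- The `.ts` reader supports only equal-length series and maps two-class
  labels to {0, 1}; multiclass files parse to integer codes but model
  fitting is binary-only.

## Known limitations

Single recurrent layer, no LSTM/GRU variants; no cross-validated lambda
selection or stability selection; no GPU path; per-lag skip connections not
implemented; MCAR missingness only in the generator. The education-level
association in the bundled contingency fixtures is intentionally absent:
the published statistic for that row is inconsistent with its published
dichotomized counts, and rather than guess the grouping actually tested,
the package reproduces only the rows that are arithmetically consistent.
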