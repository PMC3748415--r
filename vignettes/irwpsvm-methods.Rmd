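---
title: "Sparse linear SVMs by iterative p-norm reweighting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse linear SVMs by iterative p-norm reweighting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irwpsvm)
```

## The model

Given training pairs $(x_i, y_i)$, $x_i \in \mathbb{R}^n$,
$y_i \in \{-1, +1\}$, `irwpsvm` fits the linear maximum-margin classifier
whose complexity is measured by the $p$-norm penalty,

$$
\min_w \; \tfrac{1}{2}\|w\|_p^p
\quad \text{s.t.} \quad y_i(w^\top x_i - b) \ge 1, \; i = 1, \dots, m,
$$

with $0 < p \le 2$ (soft-margin slack added when the box constraint is
finite; see below). For $p = 2$ this is the ordinary L2 SVM; for $p = 1$
the L1 (lasso-type) SVM; for $0 < p < 1$ the penalty is the *bridge*
penalty, a quasi-smooth surrogate of the L0 count of nonzero weights.
Small $p$ therefore drives the weights of uninformative features to zero
and the classifier performs *embedded* feature selection — the situation
of interest in gene-expression classification, where a handful of genes
carry signal among thousands of noise dimensions.

For $p < 2$ the problem is nonconvex (for $p < 1$ not even quasi-convex),
so it is solved by **iterative reweighting** (a majorize–minimize
scheme). Writing $|w_j|^p \le$ (quadratic tangent majorizer at the
current iterate $w^{(t)}$), each outer iteration minimizes the weighted
quadratic penalty $\tfrac{1}{2} w^\top V^{(t)} w$ under the same margin
constraints, with

$$
V^{(t)} = \mathrm{diag}\!\left[(|w^{(t)}_j| + \varepsilon)^{\,p-2}\right].
$$

Coordinates that were small in the previous iterate are penalized more
strongly, and under the bridge penalty collapse to numerical zero within
a handful of iterations. Each weighted problem is convex; its Wolfe dual
is the QP

$$
\min_a \; \tfrac{1}{2} a^\top Q a - \mathbf{1}^\top a, \qquad
Q_{ij} = y_i y_j \, x_i^\top V^{-1} x_j, \qquad
0 \le a_i \le C, \;\; \textstyle\sum_i a_i y_i = 0,
$$

from which the primal is recovered as $w = V^{-1} X^\top
\mathrm{diag}(Y)\, a$ and the bias as the support-set average $b =
\frac{1}{|S|}\sum_{k \in S} (w^\top x_k - y_k)$, $S = \{i : a_i >
\texttt{support\_threshold}\}$. Prediction is
$\hat{y} = \mathrm{sign}(w^\top x - b)$, with a margin of exactly zero
mapped to $+1$.

The dual is solved by **sequential minimal optimization**: working sets
of exactly two variables chosen by the maximum-violating-pair rule
(largest $-y_i g_i$ over the "up" set against the smallest over the
"down" set, $g = Qa - \mathbf{1}$), each pair solved in closed form
along the equality-feasible line and clipped to the box. The solver is
compiled (Rcpp); the pure-R primitives `max_violating_pair()` and
`two_variable_update()` expose the same semantics for inspection and
testing.

## Tunable parameters

All knobs live in `irwp_control()`:

* **`p`** (argument of `irwp_svm()`, default 0.8) — the norm exponent.
  Smaller values give sparser fits; $p = 2$ recovers the dense L2 SVM.
* **`epsilon`** (default `1e-8`, unitless) — the reweighting smoother.
  The raw weight $|w_j|^{p-2}$ diverges as $w_j \to 0$ for $p < 2$;
  $(|w_j| + \varepsilon)^{p-2}$ caps a dead coordinate's weight at
  $\varepsilon^{p-2}$ (about $10^{12}$ at $p = 0.5$), which removes it
  from the next QP without a division by zero. Any value several orders
  of magnitude below typical weight magnitudes behaves identically.
* **`box_c`** (default 10) — the soft-margin box constraint $C$. The
  hard-margin formulation ($C = \infty$, available as `box_c = Inf`)
  requires linearly separable data and errors otherwise. On the
  synthetic benchmark below the training splits are separable in sample
  and no dual coefficient reaches 10, so the default reproduces the
  hard-margin solution exactly while remaining safe on overlapping
  inputs.
* **`outer_tol`** (default `1e-4`) — outer convergence threshold on the
  relative weight change $\|w^{(t+1)} - w^{(t)}\| / \max(1,
  \|w^{(t)}\|)$; **`max_outer_iters`** (default 50) caps the loop. At
  $p = 2$ the reweighting is the identity and the loop terminates after
  two passes; at $p \approx 1$ flat directions of the L1-type problem
  can make the iterates wander between near-equivalent solutions, and
  the cap may bind. The fit is then flagged `converged = FALSE` and is
  still usable.
* **`smo_tol`** (default `1e-6`) / **`max_smo_passes`** (default
  `2e5`) — inner KKT-violation tolerance and pair-update budget.
* **`support_threshold`** (default `1e-8`) — dual coefficients above
  this count as support vectors; the literal "$a_i \neq 0$" is
  numerically unusable.
* **`feature_threshold`** (default 0.1) — a feature is *selected* when
  $|w_j| > 0.1 \max_j |w_j|$, i.e. its weight is within an order of
  magnitude of the largest. A near-zero cutoff would be equivalent for
  bridge-penalty fits (discarded weights are numerically zero there)
  but degenerates for dense fits: at $p = 2$ every feature has a
  nonzero weight, and only a coarse relative rule yields a meaningful
  selected set across the whole $p$ range — which is what makes the
  selected-feature count comparable between $p = 0.25$ and $p = 2$ in
  the experiment grid.

## Initialization and determinism

The outer loop starts from $w^{(0)} = \mathbf{1}$, so $V^{(0)} \propto
I$ and the first inner solve is the plain L2 SVM: deterministic, and a
sensible basin for the subsequent reweighting. Inner solves are
warm-started from the previous iteration's $a$ (always feasible, since
the box and equality constraint do not change); this cuts solver effort
several-fold and does not alter the outer path, because the primal
weights recovered from *any* optimal $a$ of a weighted dual are unique.
All stochastic steps (data generation, splitting, trial scheduling) are
pure functions of explicit seeds.

## Numerical choices

* **Q-matrix construction.** $Q$ is built densely per outer iteration
  (in-scope problems have at most a few thousand samples). Features
  whose inverse reweight $1/v_j$ falls below $10^{-14}$ of the largest
  are omitted from the build: their contribution is ~8 orders of
  magnitude below `smo_tol`, and the pruning makes late iterations of
  sparse fits nearly free.
* **Degenerate pair curvature.** When the two chosen points coincide,
  the pair direction has zero curvature; the update then moves to the
  better feasible endpoint (the standard Platt fallback, realized by
  the clipping step).
* **Gradient drift.** The incrementally maintained dual gradient is
  recomputed from scratch every 1000 updates, and once more before the
  reported objective and KKT violation.
* **Unbounded duals.** Under a hard margin on non-separable data the
  dual diverges; the solver detects coefficients beyond $10^8$ and
  raises an error advising a finite `box_c`.
* **Ties.** `predict()` maps a zero margin to $+1$; `select_p()` breaks
  equal validation errors toward the smaller (sparser) $p$.

## The synthetic benchmark

`generate_weston()` reproduces a classic feature-selection benchmark
with known ground truth. Labels are $\pm 1$ with equal probability; six
of 100 features are relevant. Per sample, a coin with probability 0.7
(drawn independently of the label) decides which of two blocks carries
the signal: the signal triplet is drawn from $y\cdot N(3,1)$,
$y\cdot N(2.2,1)$, $y\cdot N(1.4,1)$, the idle triplet from $N(0,1)$,
and the remaining 94 features from $N(0, 20)$ (variance 20 — the
convention of this benchmark family; immaterial after standardization).
"Drawn successively" is read as conditional independence of the three
signal coordinates given the label and the coin; no serial correlation
is introduced.

Standardization (`standardize()`) maps each feature to mean zero and
unit SD (denominator $m$), fitted on the *training* split only and
applied unchanged to validation data — fitting on the pooled data would
leak validation information into the scaler.

The experiment harness (`run_experiment()`) regenerates a fresh
1000-sample dataset per trial (trial $t$ under sub-seed
$(s \cdot 100003 + t \cdot 999331) \bmod 2147483629$ of the master seed
$s$), splits it 250/500/750 vs the rest, and records both criteria:

* **prediction error** — percent misclassified validation samples;
* **feature-selection error** — percent symmetric difference between
  the selected set and the true relevant set,
  $100\,|S_{\text{sel}} \,\triangle\, \{1..6\}| / n$. This definition is
  symmetric, bounded, and zero exactly at perfect recovery; a missed
  relevant feature and a false positive cost the same.

The packaged study sizes are 30 trials per cell for the full
$p$-grid $\{0.1, \dots, 1.0, 2.0\}$ (and 20 trials for the
selected-feature-count trend), which puts Monte-Carlo standard errors
of the error rates well below the effects of interest while keeping a
single-CPU run in the minutes range; `run_experiment()` scales to any
trial count, and `trial_ids` lets long runs be partitioned and merged
with `combine_experiments()`.

**What the generator does and does not emulate.** It captures the
high-dimensional small-signal regime — few relevant features, many
strong noise dimensions, block-structured redundancy between the two
signal triplets. It does *not* emulate gene–gene correlation beyond the
block swap, heavy-tailed expression noise, batch effects, or
class-imbalanced designs. Passing the simulation study therefore
demonstrates correct optimization and calibrated feature recovery under
the stated generative model, not performance on any particular clinical
dataset. Real (e.g. microarray) matrices can be run through the same
pipeline via `read_dataset()` and the CLI, but no results are promised
for them.

A point worth knowing when interpreting feature-selection errors: the
0.7/0.3 block swap makes the secondary triplet (features 4–6) carry
signal in only 30% of samples, and the weakest coordinate of the losing
block (mean 1.4) is the first to be dropped by strongly sparse fits.
Very small $p$ therefore tends to report five of the six relevant
features — visible as a floor of about 1% in the feature-selection
error at $p \le 0.3$. Conversely, because the bridge problem is
nonconvex, a minority of trials converge to local minima that retain a
handful of noise features at weights above the selection cutoff (the
all-ones start makes this deterministic per dataset); running the outer
loop far past its default budget reproduces the same selected sets, so
this is a property of the objective, not of early stopping. Both
effects keep the mean feature-selection error in the low single digits
rather than at exactly zero.

## Design choices that were genuinely open

* **Bias handling.** The dual retains the equality constraint
  $\sum_i a_i y_i = 0$ and the bias is recovered from the support set,
  rather than folding $b$ into an augmented weight vector — the only
  reading under which the dual, the KKT conditions and the bias formula
  are simultaneously coherent. The sign convention is
  $\mathrm{sign}(w^\top x - b)$ throughout.
* **Feature-selection rule.** No canonical rule exists for extracting a
  selected set from a dense weight vector; the order-of-magnitude
  relative cutoff above was chosen because it is scale-free, needs no
  per-dataset tuning, and behaves sensibly at *both* ends of the $p$
  range (a tiny cutoff selects all 100 features of an L2 fit).
* **Regenerate vs re-split.** Whether repeated trials should re-split
  one fixed pool or regenerate data is underdetermined; regeneration
  per trial was chosen as the cleaner estimate of protocol-level
  variability (both are available: fix the generation seed and vary
  split seeds to re-split).
* **Cold vs warm inner starts.** Warm starts chosen for speed; see
  above for why the outer path is unaffected.

## Known limitations

* Strictly linear, binary classification; no kernels, multiclass, or
  probability outputs.
* The bridge-penalty problem is nonconvex: the algorithm converges to a
  local minimum that depends on the (fixed) initialization. The
  all-ones start makes results deterministic but not globally optimal
  by construction.
* Near $p = 1$ the outer iteration may oscillate between
  near-equivalent solutions and stop at the iteration cap
  (`converged = FALSE`) with a perfectly usable fit.
* The SMO implementation has no shrinking heuristic; very large sample
  counts (beyond the few-thousand range) would want one.

## A small worked run

```{r example, eval = FALSE}
d <- generate_weston(1000, seed = 1)
sp <- split_dataset(d, 500, seed = 2)
std <- standardize(sp$train, list(sp$valid))
fit <- irwp_svm(std$train, p = 0.8)
selected_features(fit)
prediction_error_rate(fit, std$others[[1]])
```

The reproduction of the full error tables lives in
`scripts/acceptance.R` (see the README), and every claim in this
vignette about solver behavior is asserted by the test suite.
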