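---
title: "Weighted Total Score feature selection and causal path analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted Total Score feature selection and causal path analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(wtsfs)
library(dplyr)
```

## The problem

Single feature-selection methods carry single biases: a Pearson screen
misses nonlinear effects, a lasso path is unstable under collinearity, a
random forest rewards features it happened to split on. When the goal is to
pick a small, stable set of health indicators from a modest tabular study —
samples in rows, indicators in columns, one continuous outcome — it is safer
to aggregate several methods and let the data decide how much to trust each
one. `wtsfs` implements such an aggregation, the **Weighted Total Score
(WTS)**, together with the machinery around it: a search for the method
weights, a multicollinearity filter, and a causal stage that orders the
surviving indicators and tests the paths among them.

## The Weighted Total Score

Each method $i$ produces a nonnegative importance score $F_{ij}$ for feature
$j$ (signed statistics enter as magnitudes). Scores are min-max normalized
per method,

$$\tilde F_{ij} = \frac{F_{ij} - \min_j F_{ij}}{\max_j F_{ij} - \min_j F_{ij}} \in [0, 1],$$

and aggregated through an exponential map with method weights $W_i \ge 0$,
$\sum_i W_i = 1$:

$$\mathrm{WTS}_j = \sum_i W_i\, e^{\tilde F_{ij}}.$$

The exponential stretches differences near the top of each method's scale,
so two features that a method ranks first and second by a wide margin stay
separated after averaging. Every WTS lies in $[1, e]$: the lower endpoint is
attained only by a feature at every positively-weighted method's minimum,
the upper one only at every maximum. The top-$k$ features by WTS form the
selected set.

Five scorers are built in: Pearson correlation magnitude, distance
correlation (sensitive to nonlinear dependence), absolute lasso coefficients
at a cross-validated penalty, random-forest permutation importance, and
stability selection (the fraction of 100 half-sized subsamples in which a
feature enters the lasso support at a per-subsample cross-validated
penalty). All stochastic scorers are bitwise reproducible under a seed.

Two conventions are deliberate choices rather than consequences of the
formulas. First, signed scores enter as absolute values: min-max
normalization over signed values would park strongly *anti*-correlated
features at $\tilde F = 0$, which is the opposite of what a relevance score
should do. Second, a method whose raw scores are all equal has no ranking
information; its normalized row is set to zero (with a warning), which adds
the same $W_i \cdot 1$ to every feature and cannot reorder anything.
Negative permutation importances ("less useful than noise") are clipped to
zero before normalization for the same reason.

## Searching the weights and the subset size

The weights live on the $\delta$-lattice of the probability simplex
($1/\delta$ an integer; default $\delta = 0.1$). For each candidate subset
size $k$, `optimize_weights()` starts from equal weights — on the lattice
whenever the number of methods divides $1/\delta$ — and repeatedly accepts
the best *transfer move* (shifting one $\delta$ unit of weight between two
methods) that improves the objective, stopping at a local optimum or after
`max_iter` iterations. The objective is the cross-validated MSE of a linear
least-squares fit of the min-max-scaled target on the min-max-scaled top-$k$
subset, with ties broken by higher $R^2$, then smaller $k$, then the
lexicographically smallest weight vector — a total preorder, so the winner
is unique and the whole search is deterministic under a seed.

Design choices worth stating explicitly:

* **Evaluation model.** Cross-validated linear regression (5 folds by
  default) is the simplest evaluator consistent with min-max-scaled targets;
  it is also fast enough that the search dominated by ranking, not fitting.
  The fold assignment depends only on the seed and $n$, never on the subset,
  so subset metrics are comparable and the comparison is paired.
* **Scaling before, not inside, cross-validation.** Features and target are
  min-max scaled globally, mirroring the normalization convention of the
  score table. `scale = "none"` switches to raw units.
* **Greedy vs exhaustive.** The transfer-move neighborhood makes every
  lattice point reachable, but hill climbing can still stall on plateaus
  where several weightings select the same subset. `search = "exhaustive"`
  scores the entire lattice and is the oracle the test suite compares the
  greedy search against on small lattices; `restarts = "vertices"` adds one
  restart per single-method vertex for the greedy mode.
* **Nested search order.** $k$ is the outer loop and the weights the inner
  one; the global winner is chosen by the same objective order across all
  $(k, W)$ pairs visited.
* **Memoization.** Distinct weight vectors frequently select identical
  subsets, so evaluations are cached under the sorted subset; with caching
  on or off the results are identical (the cache stores final metric rows,
  nothing stateful).

Because the equal-weight point is both the greedy start and a lattice point,
the optimized MSE can never exceed the equal-weight baseline's — the
comparison tables produced by `optimize_weights()` (`$baselines`) make that
explicit, alongside each single method's best-$k$ row.

## Multicollinearity filtering

Selected features are screened with a Spearman correlation matrix
(`spearman_matrix()`) and pruned with iterative variance-inflation-factor
removal (`prune_by_vif()`): compute $VIF_j = 1/(1 - R^2_j)$ for every
feature, and while any exceeds the threshold (conventionally 10), drop the
largest and recompute — removing one member of a near-duplicate pair
deflates the survivor, which is why recomputation after every removal
matters. Ties take the earliest column, so the procedure is deterministic.
VIF is invariant to affine rescaling, so it is computed on the data as
loaded. A feature perfectly explained by the others reports `Inf` rather
than an error.

## The causal stage

On the pruned set plus the outcome, `lingam_order()` estimates a causal
order under the linear non-Gaussian acyclic model: the most exogenous
variable is the one minimizing the total distance correlation between
itself and the residuals of the other variables regressed on it; it is
appended, the others are replaced by those residuals, and the step repeats.
Identifiability needs non-Gaussian noise — with Gaussian data both
directions fit the covariance equally well, and the returned order is
arbitrary. Since distance correlation costs $O(n^2)$, the independence
statistic is evaluated on a deterministic seeded subsample of at most
`dcor_max_n = 2000` rows; coefficient estimation always uses every row.

`lingam_fit()` then regresses each variable on all its predecessors and
keeps edges with Wald $p < \alpha$ (default 0.05), giving a DAG by
construction. `fit_path_model()` fits the recursive linear path model
implied by a set of edges by maximum likelihood on the covariance matrix of
the min-max-scaled variables. For a recursive model with uncorrelated
residuals the ML point estimates coincide with equation-wise least squares;
the standard errors are taken from the expected Fisher information of the
covariance-structure likelihood evaluated at the model-implied covariance,
with the variances and covariances of the exogenous variables held at their
sample values. When a model omits a correlation the data contain (say, a
predictor correlates with an endogenous variable beyond what its modeled
parents explain), these information-based standard errors are smaller than
the per-equation OLS ones — that is a property of the estimator, not a
bug, and it is the convention SEM software reports. The $z$ statistics are
invariant to per-variable affine rescaling, so the scaling choice
(`minmax`, `standardize`, `none`) affects estimates but not conclusions;
interpretation should therefore rest on $z$ and $p$, not raw estimates,
unless the scaling is fixed. A variable with numerically zero residual
variance makes the model singular and is rejected with an error.

## Worked example: the diabetes benchmark

The classic open dataset of 442 diabetes patients (10 baseline variables,
disease progression after one year as `Target`) ships with the package:

```{r diabetes}
d <- load_diabetes()
vif <- compute_vif(d, c("LTG", "BMI", "TC", "ABP", "LDL", "sex", "GLU"))
vif
max(vif$vif)  # all below the conventional threshold of 10
```

The six-path recursive model over the strongest indicators:

```{r sem}
paths <- data.frame(
  from = c("GLU", "LTG", "TC", "LTG", "ABP", "BMI"),
  to   = c("LTG", "TC", "LDL", "Target", "Target", "Target"))
fit_path_model(d, paths)
```

Every path is significant at any conventional level; the cholesterol link
TC &rarr; LDL is by far the strongest ($z \approx 43$).

## What the synthetic generators emulate — and what they do not

`sim_regression()` produces independent (optionally pairwise-correlated)
Gaussian features with a linear target, the structure under which planted
relevant features are recoverable by all five scorers; `sim_wdlike()` is a
preset shaped like a small wearable-device study (16 features, two
near-duplicate pairs at $r \approx 0.95$ and $0.9$, about 150 samples).
`sim_lingam()` draws from $x = Bx + e$ with uniform or Laplace noise for
the causal stage. Defaults were chosen once as representative of the small
observational health studies this framework targets. The generators do not
model repeated measures within participants, non-stationarity, measurement
floors/ceilings, or raw time series — so green tests certify the
algorithms' contracts under their stated assumptions, not performance on
any particular real cohort.

Problem sizes used in the package's own checks: property suites run on
randomized tables of up to 5 methods and 9 features (1000 cases);
optimizer checks use $n \approx 80$–$150$, $p \le 8$; causal-recovery
checks use 3-variable chains at $n = 2000$ (ordering, 50 replicates) and
$n = 5000$ (coefficients). These sizes give stable pass/fail behavior for
the stated thresholds (order accuracy $\ge 90\%$, coefficient RMSE
$\le 0.05$).

## Numerical conventions and limitations

* Weight vectors are validated to sum to 1 within $10^{-9}$ absolute;
  internally they are integer multiples of $\delta$, so transfer moves are
  exact.
* WTS ties are broken by original column order (stable), making selections
  bitwise reproducible.
* Rank-deficient training folds drop aliased columns (coefficient 0) rather
  than failing.
* The greedy weight search is a local method; on plateaus it may return a
  different weight vector than the exhaustive oracle while matching its
  objective value. Equality of the full result is only guaranteed (and only
  asserted) on the small lattices where the oracle runs.
* The causal stage assumes linear relations, non-Gaussian independent
  noises, and no latent confounders; it reports path-level tests only, not
  global fit indices.
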