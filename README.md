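# wtsfs

Ensemble feature selection by exponential **Weighted Total Scores**, with a
weight-simplex search, multicollinearity pruning, and a downstream causal
stage (LiNGAM-style ordering plus recursive path-model significance tests).

## Who this is for

Analysts of small-to-medium tabular studies — health indicators, wearable
summaries, clinical baselines — who need (a) a small, defensible feature set
for predicting a continuous outcome, and (b) an interpretable directed graph
of how the selected indicators relate to the outcome and to each other. No
single feature-selection method is trustworthy alone; `wtsfs` aggregates
five of them and learns how much to trust each.

## The method

Per-method importance scores \(F_{ij}\) (Pearson |r|, distance correlation,
|lasso coefficients| at a CV penalty, random-forest permutation importance,
stability-selection frequency) are min-max normalized per method to
\(\tilde F_{ij} \in [0,1]\) and aggregated as

```
WTS_j = Σ_i  W_i · exp(F̃_ij),     W_i ≥ 0,  Σ_i W_i = 1,
```

so every WTS lies in `[1, e]`. The weights live on a δ-lattice of the
probability simplex and are found by greedy hill climbing (single-δ weight
transfers between methods, equal-weight start, optional vertex restarts,
exhaustive mode for small lattices), jointly with the subset size k, to
minimize cross-validated MSE of a linear fit on the top-k features
(ties: higher R², then smaller k). Subset evaluations are memoized. Selected
features are screened by Spearman correlations and pruned by iterative
VIF removal at threshold 10; the survivors enter a DirectLiNGAM-style
causal ordering (iterative exogeneity search with distance correlation as
the independence measure), Wald-pruned OLS edges along the order, and a
recursive path model whose per-path z and p values come from the expected
Fisher information of the covariance-structure ML fit.

## Worked example

The classic open 442-patient diabetes study (10 baseline variables; outcome
`Target` is disease progression after one year) is bundled:

```r
library(wtsfs)
d <- load_diabetes()

compute_vif(d, c("LTG", "BMI", "TC", "ABP", "LDL", "sex", "GLU"))
#>   feature   vif
#> 1     LTG 2.318
#> 2     BMI 1.507
#> 3      TC 8.809
#> 4     ABP 1.391
#> 5     LDL 7.400
#> 6     sex 1.237
#> 7     GLU 1.451
```

All seven VIFs sit below the conventional threshold of 10, so no feature is
dropped (TC and LDL come closest — total and LDL cholesterol are strongly
correlated). Fitting and testing the six-path recursive model over these
indicators:

```r
paths <- data.frame(
  from = c("GLU", "LTG", "TC", "LTG", "ABP", "BMI"),
  to   = c("LTG", "TC", "LDL", "Target", "Target", "Target"))
fit_path_model(d, paths)
#>   from     to estimate std_err      z   p_value
#> 1  GLU    LTG   0.4892 0.04434 11.032 2.664e-28
#> 2  LTG     TC   0.4769 0.03771 12.648 1.149e-36
#> 3   TC    LDL   0.8005 0.01880 42.581 0.000e+00
#> 4  LTG Target   0.4400 0.04601  9.562 1.152e-21
#> 5  ABP Target   0.1997 0.04638  4.306 1.660e-05
#> 6  BMI Target   0.4900 0.04948  9.903 4.021e-23
```

Every path is significant; the strongest is total → LDL cholesterol
(z ≈ 42.6), and disease progression is driven most by log-triglycerides
(LTG) and BMI. Estimates are on min-max-scaled variables; z and p are
scale-invariant.

The full selection pipeline on synthetic wearable-style data:

```r
d <- sim_wdlike(n = 200, seed = 42)                 # 16 features, 2 collinear pairs
fit <- optimize_weights(d, "y", seed = 42, k_range = 1:10)
fit
#> Weighted Total Score selection
#>   k* = 6, selected: x1, x3, x5, x7, x9, x12
#>   W* = pearson=0, distance=0, lasso=0, rf=0, stability=1
#>   MSE 0.004523  RMSE 0.06725  MAE 0.05353  R2 0.8385  EV 0.8385
#>   1194 evaluations (1161 cache hits), 85 greedy iterations
```

The four planted predictors (x1, x3, x5, x7) are all selected, the
near-duplicate copies (x2, x6) are not, and the optimized weights beat or
match every single-method and equal-weight baseline (`fit$baselines`).
`tidy(fit)`, `glance(fit)` and `autoplot(fit)` expose the ranking, the
metric summary and a ranking plot; `prune_by_vif()`, `lingam_fit()` and
`fit_path_model()` continue the pipeline, and `export_graph()` writes DOT
and CSV edge lists. A thin command-line front end with the same verbs lives
at `inst/cli/wtsfs.R`.

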