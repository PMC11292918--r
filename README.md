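# clogitforest

Random forests for matched case–control studies, built from conditional
logistic regression trees.

## Why

In a 1:m matched case–control study every case comes with m controls that
share its matching variables (age, district of residence, ...). The
standard analysis, conditional logistic regression (CLR), eliminates the
stratum effects by conditioning on "one case per stratum": the likelihood
contribution of stratum *i* is

    P_i = exp(eta_case) / sum_j exp(eta_ij),      eta_ij = x_ij * beta + f(z_ij)

so only within-stratum contrasts matter. CLR takes `f` linear. This package
replaces `f` with likelihood-guided trees and bags them:

* `fit_clr()` — ridge-penalized CLR via Newton iteration on the conditional
  likelihood (the numerical core everything else shares);
* `clogit_tree()` — recursive partitioning embedded in the CLR framework:
  `f(z) = sum_t delta_t I(z in S_t)`, grown by exhaustively scoring every
  (node, variable, threshold) candidate through a joint refit, with an
  optional dedicated exposure effect `x * beta` and BIC pruning
  (`prune_bic()`) for standalone use;
* `clogit_forest()` — the ensemble: stratum-level subsampling (63.2%
  without replacement, or bootstrap), per-split mtry decorrelation,
  unpruned base learners, predictions averaged on the log-odds scale and
  the exposure estimate `beta_bar` averaged across trees; optionally each
  tree grows on top of the linear CLR fit of all covariates
  (`offset = "linear"`), so splits only capture non-linearity and
  interactions;
* `variable_importance()` — permutation importance scored by the drop in
  mean per-stratum predictive conditional likelihood (out-of-bag variant by
  default), and `boot_ci()` — nonparametric stratum-bootstrap percentile
  intervals for the exposure effect;
* `dgp_config()` / `simulate_matched_study()` / `run_comparison()` — a
  synthetic-data generator for district-matched study designs (linear,
  tree-structured and smooth covariate effects; signal/noise mixes; 1:3
  matching) plus the comparison harness computing the two quality measures
  (out-of-sample predictive conditional likelihood, absolute exposure-effect
  error) and a 10-fold stratum-level CV mode (`cv_cond_likelihood()`).

## Worked example

```r
library(clogitforest)

cfg <- dgp_config("B", n_signal = 5, n_noise = 5, preset = "reduced")
sim <- simulate_matched_study(cfg, seed = 2024)
sim$study
#> Matched case-control data: 100 strata, 400 subjects (stratum sizes 4-4)
#> Exposure: present (53.2% exposed)
#> Covariates: 10 (z1:bina, z2:bina, z3:cont, ...)

fit <- clogit_forest(sim$study, control = forest_control(ntree = 50, seed = 1))
fit
#> Conditional logistic regression forest: 50 trees, mtry = 3, sampling = subsample
#> Exposure effect: beta_bar = 0.9282 (OR = 2.530)
#> Terminal nodes per tree: 6.3 (range 5-8)

variable_importance(fit, sim$study, variant = "oob", seed = 1)
#> Permutation variable importance (oob variant, 1 permutation(s))
#>  variable    importance
#>        z2  0.0279176391
#>        z3  0.0275068517
#>        z9  0.0072695389
#>        ...

eta <- predict(fit, sim$validation)
pred_cond_likelihood(sim$validation, eta)$mean
#> [1] 0.405
```

The generator's truth for this seed used `z2, z6, z9, z3, z10` as signal
variables and `beta = log 2 = 0.693`. The forest estimates the exposure
odds ratio at 2.53 (true 2.0), ranks signal variables `z2`, `z3`, `z9` at
the top, and identifies the true case in 40.5% of validation strata where
guessing gives 25% and CLR on the same data reaches 36.0% — the
tree-structured covariate effects are exactly what a linear model misses.

A thin command-line interface over the same functions ships in
`inst/cli/clogitforest.R` (subcommands `simulate`, `fit`, `predict`,
`importance`, `ci`, `tree`, `compare`; every run writes its resolved
configuration next to its output).

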