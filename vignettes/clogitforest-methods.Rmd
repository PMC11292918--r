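---
title: "Conditional logistic regression forests: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional logistic regression forests: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A 1:m matched case–control study pairs each diseased case with m controls
that share its matching variables (age band, district of residence, ...).
Cases and their controls form *strata*; members of a stratum are not
independent, and matching variables with many levels (such as residence
area) cannot be adjusted for by ordinary regression. The standard analysis
is conditional logistic regression (CLR),

$$\log\frac{P(y_{ij}=1)}{P(y_{ij}=0)} \;=\; \alpha_i + x_{ij}\beta + \mathbf{z}_{ij}^{\top}\boldsymbol\gamma,$$

where $\alpha_i$ is the effect of stratum $i$, $x$ a dedicated binary
exposure with log odds ratio $\beta$, and $\mathbf z$ the remaining
covariates. Conditioning on "exactly one case per stratum" eliminates the
$\alpha_i$: the contribution of stratum $i$ with members
$j = 1,\dots,m_i$ is the softmax probability

$$P_i \;=\; \frac{\exp(\eta_{i,\mathrm{case}})}{\sum_{j=1}^{m_i}\exp(\eta_{ij})},$$

which depends only on within-stratum differences of the linear predictor
$\eta$. Nothing in this package ever represents an $\alpha_i$; every model
is fitted and scored through this conditional likelihood.

CLR assumes linear, additive covariate effects. This package implements two
relaxations built on the same likelihood:

* **conditional logistic regression trees** — the covariate effect is a
  step function $f(\mathbf z) = \sum_t \delta_t\, I(\mathbf z \in S_t)$
  over terminal nodes $S_1,\dots,S_t$ found by likelihood-guided recursive
  partitioning, optionally alongside the linear exposure term
  $x\beta$; and
* **conditional logistic regression forests** — a bagged ensemble of such
  trees with stratum-level resampling and mtry decorrelation, whose
  prediction is the average of the per-tree linear predictors and whose
  exposure estimate $\bar\beta$ is the average of the per-tree $\hat\beta$.

## Estimation

All fits maximize the penalized conditional log-likelihood
$\ell(\theta) - \tfrac{\lambda}{2}\lVert\theta\rVert^2$ by full Newton
iteration with analytic gradient and Fisher information and step-halving.
Defaults: iteration cap 100, relative objective tolerance `1e-10`, gradient
max-norm tolerance `1e-8`. The ridge weight $\lambda$ defaults to `1e-20`:
it is irrelevant away from separation, but keeps the optimum finite when a
tree separates cases from controls, and pins the shift-invariant node
effects (the conditional likelihood cannot distinguish $\delta$ from
$\delta + c$) at their minimum-norm representative. Numerical choices worth
knowing:

* the Newton solve adds a fixed `1e-10` Tikhonov term to the Fisher matrix
  so the exactly singular shift direction does not break the factorization;
  iterates started at zero stay on the minimum-norm representative;
* a divergence guard caps every coefficient at ±50 on the log-odds scale
  and flags the fit (`$flagged`) — a coefficient that large means
  separation, not information;
* by default the ridge applies to *all* coefficients including $\beta$
  (`penalize_exposure = TRUE`); at `1e-20` this is numerically
  inconsequential, and the mask is configurable.

Per-stratum probabilities are computed with max-subtraction, which makes
the per-stratum shift invariance hold bitwise for the stabilizing shift and
to rounding for any other constant shift.

## Tree growth

Trees grow best-first and globally: each iteration draws a fresh mtry
subset of covariates (one draw applied to all nodes; a per-node variant is
available via `mtry_per_node`), enumerates every candidate split — midpoint
thresholds between consecutive distinct observed values within each
eligible terminal node — and scores each candidate by *jointly refitting
all node effects and the exposure effect* on the augmented indicator
design. The candidate with the largest penalized gain is accepted if the
gain exceeds `epsilon` (`1e-8`, a numerical guard) and the size constraints
hold. Ties are broken by lowest variable index, then smallest threshold,
then node index, so fits are reproducible by construction. During the
search each candidate refit is warm-started from its neighbour and
truncated at `search_maxit = 4` Newton steps (tolerance `1e-7`); the
accepted split is always refit to full convergence. We measured identical
split selections against a near-exact search budget at about 30% less
cost; the truncation can in principle reorder near-ties, which the
deterministic tie-breaking makes reproducible either way.

Ordinal covariates enter as consecutive integer codes and are split like
numeric variables — no pre-dichotomization is needed or wanted. Standalone
trees are pruned by BIC ($-2\ell + \mathrm{df}\,\log n$ with
$\mathrm{df} = t - 1 + [\text{exposure}]$, $n$ = number of strata, the
minimizing prefix of the growth sequence refit at its size). Trees inside a
forest are never pruned.

### Why the base learners are depth-limited

Random-forest folklore says base learners should overfit freely. In the
conditional likelihood that advice fails in a specific way: an unbounded
tree can push the fit towards *within-stratum separation*, where node
effects and the exposure effect diverge jointly (the guard at ±50 then
binds) and the per-tree $\hat\beta$ inflates far beyond the truth. On
linear-truth synthetic data at our test scale, unlimited-depth trees with
tiny node-size floors gave single-tree $\hat\beta$ up to 6 when the truth
was $\log 2 \approx 0.69$, and forest averages of 3–5. The package
therefore defaults to `max_depth = 4`, `min_split_n = 60` rows and
`min_bucket_n = 20` rows: deep enough for rich interaction structure (up
to 16 terminal cells per tree, decorrelated across the ensemble), shallow
enough that per-tree estimates stay finite and sane (observed single-tree
$\hat\beta$ 0.4–1.3 under the same conditions, and forests on
tree-structured truth still clearly beat CLR in predictive conditional
likelihood). All three controls are ordinary tuning parameters and can be
relaxed.

## The forest

* **Resampling** operates on whole strata, never rows. The default is a
  63.2% subsample without replacement — 63.2% being the expected unique
  fraction $1 - e^{-1}$ of an n-out-of-n bootstrap — because it avoids
  deciding how a duplicated stratum should be weighted in the likelihood.
  Bootstrap mode is available; there a stratum's likelihood contribution
  counts once per draw.
* **mtry** defaults to $\max(2, \lfloor\sqrt p\rfloor)$ and can be tuned
  internally (`mtry = "tune"`): candidates 2..p are each fitted with
  `ntree_tune` trees under the same seed (so candidates share resamples)
  and scored by the mean out-of-bag predictive conditional likelihood;
  ties go to the smallest candidate. OOB scoring is the primary criterion;
  a stratum is scored only by trees whose in-bag sample excludes it.
* **Aggregation** averages per-tree *linear predictors* (log-odds scale),
  consistent with averaging $\hat\beta$; averaging per-stratum
  probabilities instead would not commute with the exposure average.
* **Linear offset** (`offset = "linear"`): the CLR fit of all covariates
  (exposure term included in the fit, excluded from the offset) is
  computed once on the full training data and passed to every tree as a
  fixed per-row offset. Trees then only model what the linear fit leaves
  unexplained; on linear-truth data they accept few or no splits, and the
  forest inherits CLR's behaviour.
* **Determinism**: a master seed spawns one substream per tree index, so
  fits are identical for any worker count; parallelism is fork-based.

## Interpretation

**Permutation importance** of a covariate is the drop in mean predictive
conditional likelihood (probability units) after permuting its column and
re-evaluating predictions, with nothing refitted. The default variant
scores each tree on its own out-of-bag strata and averages per-tree drops
(`nperm = 1`; the per-tree average already smooths); the all-observation
variant scores the whole forest on all strata (`nperm = 5`). Permutation is
global across rows by default — it breaks both the covariate–outcome and
the covariate–stratum association, which is the conventional reading — and
a within-stratum variant is exposed for users who want to preserve stratum
composition. A separately modeled exposure is not part of the forest and
gets no importance value; a covariate used in no split (and absent from
any linear offset) scores exactly zero.

**Bootstrap confidence intervals** for $\beta$ repeat the whole forest
estimation on B stratum-level bootstrap resamples (re-tuning mtry when the
control says so) and take empirical quantiles of the B values of
$\bar\beta$. The quantile is the plain order statistic
$Q(p) = x_{(\lceil Bp\rceil)}$ with no interpolation — at B = 50 and level
0.95 the bounds are the 2nd and 49th order statistics, and the convention
matters at that size, so it is fixed and documented.

## The synthetic-data generator

The generator emulates the population behind a district-matched study: a
population of 500 000 persons uniformly distributed over 1000 districts
(the `"paper"` preset; `"reduced"` uses 20 000 / 100 / 100 and is the test
scale); per district, two independent effects drawn uniformly from
$[-2, 2]$ — one on disease, one on exposure propensity; per person, 10 or
30 standard-normal covariates of which the first two are dichotomized at 0;
exposure drawn from a logistic model in the signal covariates (coefficient
0.2 each, making them genuine confounders) and the district exposure
effect; disease drawn from
$\eta = -2 + \tau_j + \log(2)\,x + f(\mathbf z)$; finally 400 strata
sampled as one case plus three never-reused non-diseased controls from the
case's district, with an independent same-population validation study for
out-of-sample scoring. The covariate effect $f$ comes in three families —
linear (alternating ±0.4), a sum of two depth-2 decision trees with leaf
values in {−0.8, 0, 0.8}, and a sum of bounded smooth transforms (sin,
centered quadratic, tanh, cyclic, scaled to roughly common variance) — and
the assignment of covariates to signal roles is permuted every replication.
The exposure-model and $f$ parameterizations are this package's own
documented defaults, all overridable in `dgp_config()`; conclusions from
the built-in study harness are about parameter recovery and method
orderings, not about any particular published curve.

What the generator does *not* emulate: missing data, measurement error,
unordered categorical covariates, informative matching beyond district,
overmatching/selection bias, or strata with more than one case. Passing
tests on this generator therefore says nothing about those features of
real studies.

## Study harness and test scales

`run_comparison()` reproduces the two quality measures — mean per-stratum
predictive conditional likelihood on independent validation data, and the
absolute error of $\hat\beta$ — across replications, and
`cv_cond_likelihood()` provides the 10-fold stratum-level cross-validation
analogue for real data. The package's own checks run at the reduced preset
with forests of 25–50 trees: exposure recovery on linear truth uses 50
replications (CLR and offset-forest means within 3 Monte-Carlo standard
errors of $\log 2$), method orderings use 20 replications (forest above
tree and CLR on tree-structured truth per replication; offset-forest
within 0.03 of CLR on linear truth on the mean, where the two are expected
to coincide), and importance checks use 20 replications of the 5-signal /
5-noise mix. These sizes are the package's choices for a laptop-scale
verification; the generator's `"paper"` preset preserves the full-scale
constants.

## Known limitations

* Only 1:m matching with exactly one case per stratum is supported; the
  general multi-case conditional likelihood (combinatorial sums) is not
  implemented.
* Unordered categorical covariates with more than two levels must be
  recoded (ordered factors are handled natively).
* Missing covariate values are rejected, never imputed.
* Forest exposure estimates carry a small upward finite-sample tilt
  relative to CLR when trees split on noise; the linear offset removes
  most of it on near-linear data, and the bootstrap CI quantifies the
  remaining uncertainty honestly.
* No analytic variance for $\bar\beta$: uncertainty comes from the
  bootstrap only.
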