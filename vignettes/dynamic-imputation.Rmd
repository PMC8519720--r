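---
title: "Swarm-selected imputation: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm-selected imputation: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynimpute)
```

## The problem and the model

Clinical tables routinely arrive with missing cells, and the choice of
imputation method changes what a downstream classifier (a survival model, a
prognosis classifier) subsequently reports. Most pipelines impute every
variable with one method chosen a priori. `dynimpute` instead treats the
method choice as a per-variable decision variable and optimizes it directly
against what practitioners actually care about: that the classifier's
sensitivity *and* specificity after imputation stay close to what they would
have been on complete data.

The moving parts:

1. **Chain structure.** The incomplete independent variables are ordered by
   ascending missing fraction, `x_1, …, x_n`, and imputed in that order. The
   model for `x_i` is trained on the rows where `x_i` is observed, with
   predictor set `{x_1, …, x_{i-1}}` (already completed); the first variable
   is predicted from its *partner* — the second chain variable, or, for a
   chain of length one, the best-observed other independent variable. Reading
   "sorted ascending" as ascending *missingness* maximizes training data for
   the early links, whose outputs feed every later predictor. Ties are broken
   by schema column position. Variables that are complete never enter the
   chain's predictor sets; this is a deliberate restriction of the chain to
   the incomplete block (the structure the selection is defined over), and is
   one of the framework's known costs (see Limitations).

2. **Algorithm pools.** Each chain slot draws from a fixed registry: 18
   classifiers for discrete targets, 9 regressors for continuous targets
   (`predictor_registry()`). All hyperparameters are frozen — six RBF widths,
   five neighbourhood sizes, polynomial degrees 2 and 3 — so the search space
   is finite and the optimizer selects *among* variants rather than tuning
   within them.

3. **Mechanism resolution.** Little's chi-square MCAR test runs on the
   continuous block (its multivariate-normal EM estimates are undefined for
   nominal data; discrete variables are still amputed and imputed). If the
   test fails to reject at `alpha` (default 0.05), the working mechanism is
   MCAR; otherwise declared domain knowledge wins; otherwise MNAR is assumed
   — the conservative default, since MNAR is the mechanism that invalidates
   the most methods. The test runs after the high-missingness column drop,
   since dropped columns never enter any model.

4. **Fitness.** For a candidate assignment, `n_repeats` times: delete cells
   from the fully observed (observational) block according to the resolved
   mechanism and the real per-variable missing fractions (`ampute()`), impute
   with the candidate chain, and compare the stratified cross-validated
   metric panel of the imputed block against the intact block *on the same
   fold draw*. The fitness is the pair of mean absolute differences
   `(|Δsensitivity|, |Δspecificity|)`, both minimized. Pairing the two panels
   on one fold draw is essential: with independent folds the difference is
   dominated by fold noise, and the defining property — restoring the true
   values gives exactly (0, 0) — would fail. Confusion counts are pooled
   across folds into a single panel per pass; per-fold panels on 10–20-record
   folds are too often degenerate.

5. **The swarm.** Particles live in `[0,1]^n`; coordinate `j` maps to a pool
   index by `min(n_pool, floor(x·n_pool) + 1)` — a surjective, monotone,
   equal-cell partition pinned by the worked anchor `x = 0.75 → index 14`
   (9-NN) in the discrete pool. The velocity update is the classic two-term
   attraction toward the personal best and a leader with unit carry-over (no
   inertia weight; an `inertia` multiplier exists and defaults to 1 so the
   literal rule is the default), clamped symmetrically to
   `vmax = δ·(range)`, `δ(i) = 0.9^i`. Mutually non-dominated
   `(Δsens, Δspec)` pairs accumulate in a Pareto archive (capacity 100,
   crowding-distance pruning); each particle's leader is drawn uniformly
   from the archive. Termination: the maximum particle distance to the
   termination leader, normalized by the initial swarm diameter, falls below
   `rnorm_threshold` (default 0.01), or `max_generations` (default 50) is
   reached. Because only the decoded index vector matters and the fitness
   seed is shared, fitness values are memoized per decoded assignment — a
   pure speedup with bit-identical results.

6. **Final selection.** Every distinct archived assignment is re-scored for
   plain classification accuracy on fresh seeded amputation draws
   (`select_repeats`, default 5 — a single draw made the accuracy argmax
   essentially random at desk scale) and the best is returned; exact ties
   break uniformly at random.

## Parameters that matter

| Parameter | Default | Meaning / why |
|---|---|---|
| `n_particles` | 100 | swarm size; 10–20 suffices for chains of 1–3 variables since the decoded space is small |
| `c1`, `c2` | 2, 2 | classic acceleration coefficients; the update rule fixes no values |
| `delta_decay` | 0.9 | geometric clamp decay, `δ(i) = 0.9^i` |
| `rnorm_threshold` | 0.01 | swarm-collapse tolerance ("normalized diameter approaches 0") |
| `n_repeats` | 100 | amputation/imputation cycles per fitness value; tests use 2–5, which suffices only because assignments are compared on common random draws |
| `alpha` | 0.05 | MCAR test level |
| `drop_threshold` | 0.5 | variables with more missingness are dropped before anything else |
| `select_repeats` | 5 | accuracy re-scoring draws in the final selection |

The downstream classifier inside the fitness loop is logistic regression
(discrete pool entry 17) by default: deterministic, cheap, and the same model
family the motivating analyses use for the final outcome model. It is
configurable wherever it appears.

## Numerical choices and degenerate inputs

* EM (Little's test and the EM imputer): convergence when the observed-data
  log-likelihood changes by less than `1e-6` (relative), cap 500 iterations,
  ridge `1e-8` on covariance diagonals; a singular pattern-restricted
  covariance is an error advising the user to drop collinear columns. A
  single missingness pattern makes the test vacuous — reported as
  not-applicable and treated as MCAR-consistent.
* Amputation deletes exactly `round(fraction · n)` cells per variable. MAR
  weights are `plogis(z)` on the driver's z-score (weighted sampling without
  replacement); MNAR deletes the most extreme values of the variable itself,
  upper tail by default (`lower`/`both` configurable); MNAR ties break by row
  position, so the operation is fully deterministic given the seed.
* Discrete predictors are passed to learners as integer level codes (levels
  fixed from the full column, so train/query always agree); the discrete
  *target* stays a factor and predictions can only be observed training
  levels. Most discrete clinical variables in the motivating tables are
  ordinal, which is what integer coding assumes.
* SVM/SVR, k-NN, ANN, logistic and linear regression standardize predictors
  on training rows; trees and naive Bayes see the raw encoding. "RBF = c" in
  the registry is read as the kernel width `γ` of `exp(−γ‖u−v‖²)` — the most
  common single-parameter convention; it is config-overridable. The SVM
  "polynomial" row uses degree 3, "quadratic" degree 2. The ANN is one hidden
  layer of `ceil((inputs + outputs)/2)` units, 500 epochs, seeded
  initialization. The C4.5-style tree is an entropy-criterion `rpart` without
  rule post-pruning; CART uses variance reduction — both noted approximations.
* Degeneracies never abort a search: a single-level training target or
  zero-variance regression target falls back to a constant predictor; k-NN
  with fewer rows than `k` reduces `k`; an empty predictor set falls back to
  mean/mode — each with a message.
* `pbest` replaces only on strict Pareto domination (stability under
  mutual non-domination); positions are clamped to `[0,1]` after each
  position update.

## What the synthetic generator emulates — and what it does not

`simulate_clinical()` draws an equicorrelated latent Gaussian, keeps
continuous variables as latent scores, quantile-thresholds discrete variables
into 2–4 levels, and draws a binary outcome from a logistic link on the
latent scores (default coefficients: first half 1, second half 0, so feature
relevance is known). The `gastric` and `atll` presets reproduce the shapes of
the two motivating case studies — 80×15 with 8 variables missing 1.25–88.75%
(29.5% of the independent block overall), and 25×35 with 12 variables missing
4–48% — including their exact per-variable missing counts. They do *not*
attempt the clinical marginal distributions (units, ranges, level labels) of
the real tables. Passing tests on these fixtures therefore demonstrates
mechanism-faithfulness, calibration and selection behaviour under a known
generative model; it does not certify performance on any particular clinical
dataset.

## Study conditions used by the test suite

Problem sizes in the suite and the acceptance script are chosen for a
desk-scale machine: fitness uses 2–5 repeats (the common-random-numbers
pairing is what makes such small counts informative), swarms of 6–20
particles over 3–15 generations, Monte-Carlo calibration of the MCAR test at
200 replicates of n = 200, p = 4.

Two fixtures deserve explanation:

* **Selection recovery.** The check that the swarm finds a regression-family
  imputer for a linear target uses MNAR upper-tail deletion (fraction 0.4) of
  `x1 = 2·x2 + ε`. Under MCAR at modest fractions, all nine regressors impute
  a strong one-dimensional linear relation almost equally well and the
  selection signal sits below the metric panel's quantization at desk-scale
  repeat counts. Tail deletion is the regime where the families genuinely
  separate — neighbours and trees cannot extrapolate into the deleted tail,
  the linear model can — and it is also this framework's default mechanism
  assumption. The feed-forward ANN remains a close competitor (with a linear
  output layer it extrapolates almost linearly), which bounds the recovery
  rate near 60% rather than near 100%.
* **Directional benchmark.** The proposed-vs-mean comparison uses a MAR
  fixture whose incomplete variable is a *nonlinear* function of an observed
  one (`x1 = x2² + ε`) with a linear downstream classifier. A single
  imputation drawn from covariates the classifier already sees cannot add
  information, so on linear-link fixtures mean imputation is matched by any
  adaptive classifier and the comparison is a coin flip; with the nonlinear
  link the selected imputer reconstructs a feature the linear classifier
  cannot form itself, making imputation quality first-order (observed margin
  ≈ 5 accuracy points).

## Known limitations

* The chain never uses complete variables as predictors (by construction);
  when the informative covariates are complete, the chain's imputations are
  weaker than a chained-equations pass over all variables would be.
* The objectives require a binary dependent variable; records missing it are
  excluded, not imputed.
* The swarm's final accuracy-based selection is noisy at small `n_repeats`
  and `select_repeats`; at the defaults (100 / 5) it is stable, at
  desk-scale settings a ~60% recovery rate of the nominally best family is
  typical (see above).
* Little's test covers the continuous block only; an MCAR decision on a
  mostly discrete table rests on few variables.
* MNAR amputation assumes a tail direction; the direction is configurable
  but not testable from data.
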