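# dynimpute

Dynamic missing-data imputation for mixed-type clinical tables: instead of
imputing every variable with one method, `dynimpute` selects — per incomplete
variable — the best prediction algorithm from fixed pools of learners, using
a **multiobjective particle swarm optimizer (MOPSO)** whose objectives are
chosen so that a downstream classifier's **sensitivity and specificity are
jointly preserved** by the imputation.

It is aimed at biostatisticians and epidemiologists working with small-to-
medium clinical datasets (tens to hundreds of patients, 10–35 mixed discrete/
continuous variables, 5–50% per-variable missingness) where a survival or
outcome classifier must be fit after imputation and the choice of imputation
method visibly moves the operating characteristics of that classifier.

## The method

Write the incomplete independent variables, sorted by ascending missing
fraction, as `x_1, …, x_n`. Imputation is a chain of per-variable prediction
models

```
x_1 = Predict_1(x_2)
x_2 = Predict_2(x_1)
x_3 = Predict_3(x_1, x_2)
…
x_n = Predict_n(x_1, …, x_{n-1})
```

where each `Predict_i` is drawn from a fixed registry: 18 classification
algorithms for discrete targets (SVM variants, k-NN, an entropy-split tree,
a feed-forward ANN, logistic regression, naive Bayes) and 9 regression
algorithms for continuous targets (SVR, k-NN, CART, ANN, multiple
regression).

The selection of `(Predict_1, …, Predict_n)` is a search over `[0,1]^n`:
each particle coordinate maps to a pool index via
`index = min(n_pool, floor(x · n_pool) + 1)`. A particle's two-objective
fitness is computed by repeatedly **amputating** the complete ("observational")
records under the dataset's resolved missingness mechanism (MCAR / MAR / MNAR
— resolved by Little's MCAR test, declared domain knowledge, or an MNAR
default), imputing with the candidate chain, and measuring the mean absolute
change of cross-validated sensitivity and specificity against the intact
data: `(|Δsens|, |Δspec|)`, both minimized. The swarm keeps a Pareto archive
of non-dominated assignments, clamps velocities by a geometrically decaying
schedule `δ(i) = 0.9^i`, stops when the normalized swarm radius collapses,
and finally returns the archive member with the highest re-scored
classification accuracy.

Five comparison imputers (listwise deletion, mean/mode, multivariate-normal
EM, chained equations, iterative random forests) and a benchmarking harness
producing sensitivity/specificity/accuracy/PPV⁺/PPV⁻/F-measure panels are
included, along with a seeded generator of synthetic clinical fixtures with
known generative structure.

## Worked example

```r
library(dynimpute)

# a gastric-cancer-shaped synthetic fixture: 80 records, 15 independent
# variables, 8 of them missing between 1.25% and 88.75%
fx <- generate_fixture("gastric", seed = 1)
missing_fraction(fx$amputed)
#> # A tibble: 16 × 3
#>   variable n_missing fraction
#> 1 x1              58   0.725
#> 2 x2               4   0.05
#> 3 x3               1   0.0125
#> 4 x4              71   0.888
#> 5 x5              64   0.8
#> # …

ds  <- drop_high_missing(fx$amputed, threshold = 0.5)  # drop > 50% missing
run <- run_impute(ds,
                  cfg = swarm_config(n_particles = 20, max_generations = 10,
                                     seed = 1),
                  n_repeats = 10, seed = 1)
run
#> <dyn_impute_run>
#> mechanism: MCAR
#> # A tibble: 3 × 6
#>   variable vtype      index family label                       param
#> 1 x3       continuous     6 knn    9-NN                            9
#> 2 x2       continuous     8 ann    Feed-forward neural network    NA
#> 3 x8       discrete      16 ann    Feed-forward neural network    NA

glance(run$mopso)
#> # A tibble: 1 × 6
#>   generations n_evaluations archive_size best_d_sensitivity best_d_specificity
#> 1          10           193            9               2.86               3.64
```

Reading: the three retained incomplete variables are imputed in ascending-
missingness order (`x3` → `x2` → `x8`); the swarm scored 193 distinct
algorithm assignments and settled on 9-NN / ANN / ANN; the best archive
member changed cross-validated sensitivity by 2.9 and specificity by 3.6
percent points under simulated missingness. `run$imputed` is the completed
dataset; `autoplot(run$mopso)` draws the Pareto front;
`benchmark_imputers()` compares the proposed selection against the five
baselines.

A command-line front end (subcommands `impute`, `benchmark`, `simulate`,
`ampute`, `mcar-test`, `registry`) is installed at
`system.file("cli", "dynimpute.R", package = "dynimpute")`.

## Scope notes

The framework requires a discrete (binary) dependent variable — the
objectives are sensitivity/specificity changes, which are undefined for a
continuous outcome. Records missing the dependent variable are excluded, not
imputed. The synthetic presets emulate the shapes, types and missingness
profiles of the motivating case studies, not their clinical marginal
distributions.
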