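---
title: "Surrogate-assisted optimization of callus induction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-assisted optimization of callus induction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callusopt)
```

## The problem

Callus induction — the formation of undifferentiated cell mass from an
excised tissue piece placed on culture medium — is the gateway step of plant
tissue culture. Its success depends on interacting choices: which explant is
cultured (leaf, nodal segment, root or shoot), which plant-growth-regulator
(PGR) cocktail is added, how concentrated the Murashige–Skoog (MS) basal
salts are, and when the outcome is scored. Exhaustively testing such a
factorial in the laboratory is slow and expensive, so a natural strategy is
to (i) fit a cheap predictive *surrogate* of the response surface from a
replicated factorial experiment and (ii) search the surrogate with an
optimizer instead of the bench.

`callusopt` implements that strategy end to end for a discrete carrot
(*Daucus carota*) design space of

* 8 PGR treatments (combinations of 2,4-D, BAP, kinetin and NAA; treatment 8
  is the hormone-free control),
* 4 explant types,
* 3 MS strengths (1x, 4x, 8x), and
* 2 sampling days (8 and 25),

i.e. 192 culture conditions, each scored by two outputs: the **induction
percentage** (fraction of replicate pieces forming callus, 0–100) and an
**induction speed** derived from the mean callus diameter.

## Outputs and the speed formula

The induction percentage of a condition is `100 * k / n` over its
replicates. The speed is defined from the sampling day and mean diameter;
the package implements both orientations:

* `"as_written"` (default of `compute_speed()`): day / diameter, in day/mm.
  Under this form a larger callus gives a *smaller* number, so it behaves
  like a "days needed per mm" cost.
* `"inverted"`: diameter / day, in mm/day — the physically conventional
  growth rate.

Neither form is asserted as the uniquely intended one; the toggle keeps both
available. Two conventions are fixed regardless of mode: a condition with no
callused replicates has mean diameter 0 and speed 0 (never infinity), and
mean diameter averages *callused* replicates only. The optimizer always
maximizes the diameter/day desirability (or equivalently minimizes the
as-written cost); the direction is recorded in its configuration.

Diameters are assumed to be in millimetres; the unit is an assumption of
this package, not a stated fact.

## The synthetic factorial generator

Because the original laboratory replicate tables are not redistributable,
the package ships a generator (`simulate_experiment()`) whose defaults
emulate the study design: 24 replicates per condition in 3 sub-sets
(completely randomized design), with a per-condition effect table
(`default_effect_table()`) holding the induction probability `p`, the
expected diameter `mu` and its spread `sigma`.

The sampling model, per condition:

1. each sub-set draws an induction probability
   `plogis(qlogis(p) + e)`, `e ~ N(0, sd = 0.3)` — a logit-normal
   between-sub-set effect standing in for unreported variance components.
   Probabilities of exactly 0 or 1 are clamped: impossible conditions never
   produce callus, certain ones always do;
2. callus outcomes are Bernoulli draws;
3. callused diameters are normal `(mu, sigma)` truncated at zero (a gamma
   model was considered and rejected as needlessly indirect at these
   `mu/sigma` ratios); non-callused pieces have diameter 0.

A single integer seed fixes the whole output bit-exactly.

### What the default effect table encodes

The table reproduces every quantitative outcome the study reports: all 8x MS
conditions fail (p = 0); at 4x MS treatments 5–7 induce callus in every
replicate (p = 1) while 1, 2, 4 and the control never do; the hormone-free
control is inert everywhere. Qualitative orderings are honored at 1x MS
(shoot strongest in treatments 1, 2, 5, 6, 7; nodal strong in 2–6 and
weakest in 1 and 7), and the jointly best conditions are placed where the
study's optimization found them: the best percentage at (shoot, 1x,
treatment 6, day 25) and the best growth rate at (leaf, 1x, treatment 6,
day 8).

Everything else — the actual numeric values of the 1x probabilities
(0.15–1), the day-8 deficit of 0.15–0.25 relative to day 25, the 4x
treatment-3 cells (0.4/0.5), and all diameter means — is interpolated
modeling choice, not data: bar-chart values are not readable from the source
and are treated as free parameters, chosen once so that the stated orderings
and optima hold and left alone thereafter. Passing tests therefore
demonstrate that the pipeline recovers the structure this generator encodes;
they are not evidence about real carrot tissue, and features of real data
such as plate effects, contamination losses, unbalanced replication or
measurement error in diameters are not emulated.

`expected_summaries()` returns the noise-free limit (exact percentages
`100 p`, diameters `mu`), which the test suite uses for surrogate-recovery
checks.

## The MLP surrogate

`train_mlp()` fits a single-hidden-layer perceptron: 10 inputs (four PGR
concentrations, MS multiplier, sampling day, one-hot explant block), 11
hidden units (tanh by default), one output. The phrase "11 hidden layers" in
the source study is read as one hidden layer of 11 neurons — an 11-deep
network is implausible for a few hundred rows, and the study's own wording
about reporting "hidden layers along with the number of neurons in each
layer" suggests the conflation; depth is not configurable, but every other
aspect is.

Training is full-batch error backpropagation with an L2 weight-decay penalty
`alpha * sum(w^2)` on connection weights (the deterministic core of
Bayesian-regularized backpropagation; full evidence re-estimation of `alpha`
is out of scope). The update rule is a resilient variant: each weight keeps
its own step size, moves against the sign of its gradient, steps grow 1.2x
while the gradient sign persists and halve when it flips, and a whole epoch
is rejected (weights kept, all steps halved) if it would increase the
penalized loss. Consequences: the recorded loss history is monotone
non-increasing by construction, and a fixed seed (weight initialization is
the only randomness) makes training bit-reproducible.

Inputs are min–max scaled to [0, 1]; the speed target is min–max scaled and
the percentage target is fixed-scaled by 1/100.

**Output activation.** The percentage network ends in a logistic unit
(`out_activation = "auto"`); speed stays linear. An induction fraction is
bounded with true plateaus at 0% and 100%, and this choice matters for
optimization: the simulated factorial contains 25 conditions whose observed
induction is exactly 100%, so a linear-output network clipped to [0, 100]
ties all of them at the clip and its argmax is decided by fitting overshoot,
which wanders between the tied cells. On the logit scale the competition is
decided by neighborhood support — a 100% cell surrounded by 85–95% cells
outranks a 100% cell bordered by 0% cells — which is both statistically
natural (it is how a binomial link treats saturated cells) and what makes
the optimizer's reported optimum stable across simulation seeds.

Defaults: `hidden_units = 11`, `l2_alpha = 3e-4`, `max_epochs = 4000`,
90/10 train/test split. `l2_alpha = 3e-4` is sized for condition summaries
carrying binomial noise from 24 replicates; recovery tests on noise-free
data use `1e-5` since there is no noise to smooth over.

## The RBF surrogate

`fit_rbf()` implements a Gaussian radial-basis-function network: prediction
is `w0 + sum_b w_b * f(x, x_b)` with the transfer function

```
f(x_r, x_b) = exp(-(||x_r - x_b|| * 0.8326 / h)^2)
```

using the Euclidean norm; the constant 0.8326 (numerically sqrt(ln 2)) makes
the spread `h` the half-response distance. The constant is used verbatim.
Centers default to all training points, matching the equation's indexing of
observed inputs (a k-means subset is available for larger data). The study
does not state how the output weights were estimated; the package solves the
ridge-regularized linear least-squares problem on the kernel design matrix
(bias unpenalized), which is the standard statistical-RBF choice and
deterministic. With `ridge_lambda = 0` and distinct points the fit
interpolates exactly; a singular unregularized system raises an error
advising `ridge_lambda > 0`.

**Distance metric.** Features are min–max scaled so `h` is dimensionless.
On top of that, per-block multipliers (PGR concentrations, MS level,
sampling day, explant block) are selected jointly with `h` by leave-one-out
error over a small factorial grid. The blocks of this mixed
categorical/numeric space have no common natural length scale — a full
explant swap moves the one-hot block by sqrt(2) while the decisive
0 -> 0.2 mg/l PGR step moves 0.2 — and a single isotropic scale cannot serve
both; leave-one-out calibration is computed from training data only and is
deterministic. Fixing `metric_weights = c(pgr = 1, ms = 1, day = 1,
explant = 1)` recovers the plain scaled metric.

## Evaluation and sensitivity

`rmse()` and `r_squared()` are the exact textbook forms. Variable importance
(`sensitivity_analysis()`) follows the variable-sensitivity-error reading:
the baseline model's RMSE is compared with the RMSE of a model *retrained
with a variable group withheld* (same configuration and seed, isolating the
variable's effect); `VSR = VSE / baseline` ranks groups, highest first. The
source study never gives a formula for VSE/VSR, so the ratio definition is a
documented reading, not a reproduction. Groups default to the semantic
blocks {PGR concentrations}, {MS level}, {sampling day}, {explant}; a
permutation mode (shuffle a group's columns instead of retraining) is
available as a cheaper alternative, and extra columns (e.g. a known
pure-noise probe) can be appended.

## The genetic algorithm

The optimizer works on 4-gene integer chromosomes (treatment 1–8, explant
1–4, MS index 1–3, day index 1–2). Operators:

* binary tournament selection with elitism 1 (the study's description of
  selection is ambiguous; tournament + elitism is the standard reading that
  preserves convergence and makes the best-so-far history monotone),
* single-point crossover on the gene string (probability 0.9),
* per-gene uniform resampling mutation (rate 0.05; the study is silent, so a
  standard small rate is used).

Defaults follow the study's setup: population 100, 1000 generations.
Duplicate chromosomes are allowed — the space has only 192 points and
deduplication would distort selection pressure. Because the space is finite,
surrogate predictions are precomputed over the full grid once; fitness
evaluation is exact lookup, and `brute_force_optimum()` provides the
exhaustive oracle that every GA run is tested against.

Multi-objective mode maximizes predicted percentage and speed desirability
jointly with fast non-dominated sorting (ranks are 0-based; rank 0 is the
non-dominated set) and crowding-distance tie-breaks, pooling parents and
children before truncation. The study does not define its multi-objective
"fitness function value" plot, so the recorded history is a documented
choice: per generation, the maximum over the current front of the sum of
min–max-normalized objectives. The single reported compromise solution
maximizes that same normalized sum over the final front, and the rule is
named in the result (`selection_rule`). Ties anywhere resolve to the first
row in `design_grid()` order (treatment fastest, then explant, MS, day).

## Numerical and degenerate-input conventions

* Zero-diameter conditions: speed 0, never division by zero.
* Constant feature columns pass through scaling unchanged (span treated
  as 1).
* Percentage predictions are clipped to [0, 100] at the interface (a no-op
  for the logistic output).
* `p = 0` / `p = 1` cells bypass the sub-set effect entirely, so impossible
  and certain conditions stay exact in every simulation.
* All stage seeds in `run_pipeline()` derive from one global seed by fixed
  offsets, so stages are individually rerunnable yet jointly reproducible,
  and a manifest with MD5 hashes of every artifact is always written.

## Problem sizes used by the test suite

The suite simulates the full 4608-row factorial (plus one 460,800-row run
for a law-of-large-numbers check with the sub-set effect disabled, since the
3-point tolerance band tests the Bernoulli machinery, not the
overdispersion), trains surrogates on the 192 condition summaries, and runs
GA oracle-equivalence at 100–300 generations within module tests and the
full 100 x 1000 configuration (20 seeds) in the end-to-end checks.

## Known limitations and divergences

* The surrogate comparison does not reproduce the study's claim that the MLP
  predicts better than the RBF: with the leave-one-out-calibrated metric the
  RBF generalizes at least as well as the MLP on this generator's data for
  every seed examined. The pipeline emits the comparison table; superiority
  is not asserted.
* The study's 1x-MS "maximum speed in leaf and root in medium 4" narrative
  conflicts with its own reported speed optimum (leaf, 1x, treatment 6,
  day 8); the diameter means follow the optimum, not the narrative.
* Published RMSE values are typographically corrupted in the source and are
  not used as references; R-squared values are.
* Real supplementary raw data, if placed at
  `tests/testthat/raw-study-data.csv` in the canonical schema, activates the
  published-fit-quality check; without it that check reports failure by
  design rather than silently passing.
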