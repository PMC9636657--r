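# callusopt

Surrogate-assisted optimization of plant callus induction conditions.

Callus induction — coaxing an excised tissue piece (explant) to form
undifferentiated cell mass on culture medium — is the first step of plant
tissue culture, and its success depends jointly on the explant type, the
plant-growth-regulator (PGR) cocktail, the strength of the Murashige–Skoog
(MS) basal medium, and the sampling day. Testing every combination at the
bench is costly. `callusopt` is for tissue-culture researchers and
biostatisticians who instead want to (1) fit cheap predictive surrogates of
the response surface from a replicated factorial experiment and (2) search
those surrogates with an evolutionary optimizer.

The package covers a discrete carrot design space of 8 PGR treatments
(2,4-D, BAP, kinetin, NAA combinations; treatment 8 is the hormone-free
control) x 4 explants (leaf, nodal, root, shoot) x 3 MS strengths (1x, 4x,
8x) x 2 sampling days (8, 25) = 192 culture conditions, each scored by the
callus-induction percentage and an induction speed derived from mean callus
diameter.

## What it implements

* **Data model and generator** — the factorial schema (24 replicates per
  condition in 3 sub-sets), per-condition summaries, and a seeded simulator
  whose default effect table reproduces the reported outcome structure
  (complete failure at 8x MS; 100%/0% treatment split at 4x MS; the best
  conditions at 1x MS with treatment 6 = 0.5 mg/l 2,4-D + 0.5 mg/l BAP).
* **MLP surrogate** — a 10-input, 11-hidden-unit perceptron trained by
  full-batch error backpropagation (resilient per-weight steps with a
  monotone acceptance rule) under an L2 weight-decay penalty,

  `L(w) = mean((y - yhat)^2) + alpha * sum(w^2)`,

  with a logistic output for the bounded percentage target.
* **RBF surrogate** — a Gaussian radial-basis-function network,

  `yhat(x) = w0 + sum_b w_b * exp(-(||x - x_b|| * 0.8326 / h)^2)`,

  with centers at the training points and ridge least-squares output
  weights; the spread `h` (and per-block distance weights) are chosen by
  leave-one-out error.
* **Evaluation** — RMSE, R², and variable-sensitivity ranking
  (`VSE` = RMSE after retraining without a variable group,
  `VSR = VSE / baseline RMSE`; the most influential input has the highest
  VSR).
* **Discrete GA** — 4-gene chromosomes over the 192-point grid, binary
  tournament selection with elitism, single-point crossover, uniform
  mutation; single-objective mode maximizes one predicted output,
  multi-objective mode uses non-dominated sorting with crowding distance and
  reports the compromise solution maximizing the sum of min–max-normalized
  objectives. An exhaustive-enumeration oracle verifies every run.
* **Pipeline** — `run_pipeline()` chains simulate → summarize → train →
  evaluate → sensitivity → optimize, writing all artifacts plus a manifest
  with hashes; one global seed makes the whole run reproducible.

## Worked example

```r
library(callusopt)

records   <- simulate_experiment(generator_config(seed = 1))   # 4608 replicates
summaries <- condition_summaries(records, speed_mode = "inverted")

mlp_pct   <- train_mlp(summaries, "percentage", mlp_config(seed = 1))
mlp_speed <- train_mlp(summaries, "speed",      mlp_config(seed = 1))

res <- ga_optimize(mlp_pct, mlp_speed, ga_config(seed = 1, objectives = "both"))
res$front
#>   treatment_id explant ms_level sampling_day percentage     speed
#> 1            6   shoot        1           25   91.24051 0.3897901
#> 2            6    leaf        1            8   62.55615 0.7759070
#> 3            6   shoot        1            8   85.50671 0.7246405
res$selected
#>   treatment_id explant ms_level sampling_day percentage     speed
#> 1            6   shoot        1            8   85.50671 0.7246405
```

The Pareto front spans the trade-off between induction percentage and growth
rate (speed in mm/day): day-25 shoot cultures maximize the predicted
percentage (91.2%), day-8 leaf cultures maximize the predicted growth rate
(0.78 mm/day), and the selected compromise — shoot explant, 1x MS, treatment
6, sampled at day 8 — keeps 85.5% predicted induction at nearly the best
rate. All three front members sit in treatment 6 on 1x MS, the condition the
surrogates identify as globally best.

Input importance for the percentage model:

```r
sensitivity_analysis(summaries, "percentage", "mlp", cfg = mlp_config(seed = 1))
#>               group      vse      vsr rank
#> 1  ms_concentration 32.25363 2.626901    1
#> 2 pgr_concentration 30.60716 2.492804    2
#> 3      explant_type 15.33745 1.249161    3
#> 4     sampling_time 13.06673 1.064221    4
```

Removing the MS-strength input degrades the model most (VSR 2.6), sampling
time least — MS concentration is the dominant factor, consistent with the
complete failure of all 8x MS cultures.

## Layout

```
R/                      implementation (design space, generator, MLP, RBF,
                        metrics/sensitivity, GA, pipeline)
inst/extdata/           packaged PGR treatment table (CSV)
tests/testthat/         unit, property and end-to-end acceptance tests
scripts/acceptance.R    headline-quantity reproduction script
vignettes/              methods vignette (models, assumptions, design choices)
```
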