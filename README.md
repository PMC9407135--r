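# tmlesoccer

Causal inference for a question sports scientists usually answer with
associations: **does substituting a player increase the distance the whole
team covers afterwards?**  The package estimates the average treatment
effect (ATE) of a substitution in the previous five-minute period (`A`) on
the team's total distance in the current period (`Y`), adjusting for the
period index (`W1`), the number of substitutes already on the pitch (`W2`)
and whether a substitution falls inside the current period (`W3`):

    psi = E_W [ E(Y | A = 1, W) - E(Y | A = 0, W) ]

Three estimators are provided and compared:

* **GLM** — G-computation with a main-effects linear outcome model (the
  traditional comparator; `ate_glm()`);
* **TMLE** — targeted maximum likelihood: a from-scratch V-fold
  cross-validated super learner (discrete and convex-weighted continuous)
  fits the outcome regression and the treatment mechanism, then a
  one-parameter logistic fluctuation along the clever covariate
  `H = A/g(1|W) - (1-A)/(1-g(1|W))` solves the efficient influence-curve
  score equation; inference is influence-curve based (`tmle_ate()`);
* **TMLEH** — the same pipeline with a hand-picked learner roster (linear,
  pairwise interactions, stepwise, additive model, random forest,
  regression tree).

A structural simulator (`sim_config()`, `simulate_periods()`, `true_ate()`)
generates period-level data with known ground truth and is the basis of a
replication study (`run_simulation_study()`) showing the pattern that
motivates targeting: a misspecified-by-construction linear model is biased
for the ATE even with the right confounders, while the doubly robust
targeted estimators stay centered whether or not `W3` is dropped from the
adjustment set.  A positivity diagnostic, an observed-data runner, CSV/YAML
IO and a small CLI round out the toolkit.  Methodological details are in
`vignettes/targeted-substitution-effects.Rmd`.

## Worked example

```r
library(tmlesoccer)

cfg <- sim_config()                      # calibrated simulator defaults
truth <- true_ate(cfg, mc_draws = 1e6, seed = 5, norm_n = 5000)
truth
#> True ATE (normalized scale): 0.06446  [mc se 4.5e-05, 1000000 draws]
#>   raw scale: 60.34 m over expected range 936.0 m (n=5000)

dat <- simulate_periods(cfg, 2000, seed = 7)
ate_glm(dat)                             # linear-model G-computation
#> GLM (correct adjustment): ATE = 0.0803, 95% CI [0.0676, 0.0931], n = 2000
tmle_ate(dat, V = 5, seed = 3)           # targeted estimator
#> TMLE (correct adjustment): ATE = 0.0674, 95% CI [0.0582, 0.0765], n = 2000
```

The simulator's true effect is about 0.065 on the normalized distance
scale (about 60 m of team distance per five-minute period).  The linear
model overshoots by roughly a third — its main-effects form cannot
represent the curved period trend or the fact that a substitution helps
more when more fresh players are on the pitch — while the targeted
estimate sits on the truth with an honest interval.  A full replication
study aggregates this into a bias table:

```r
study <- run_simulation_study(
  study_config(replications = 50, n_per_replicate = 1000,
               estimators = c("GLM", "TMLE"), V = 5,
               tmle_roster = "reduced", master_seed = 1))
study$table[, c("estimator", "adjustment", "mean_ate", "bias_pct")]
#>  estimator   adjustment mean_ate bias_pct
#>        GLM      correct   0.0844    18.97
#>        GLM misspecified   0.0833    17.47
#>       TMLE      correct   0.0680    -4.07
#>       TMLE misspecified   0.0673    -5.15
```

To analyze a real per-period table (columns mappable to
`W1,W2,W3,A,Y`), use `read_observed()` + `run_observed_analysis()`, or the
CLI:

```sh
Rscript inst/cli/tmlesoccer simulate -n 1000 --seed 1 --out out/
Rscript inst/cli/tmlesoccer sim-study --seed 1 --out out/ --replications 50 -n 1000
Rscript inst/cli/tmlesoccer observed-study --data periods.csv --seed 1 --out out/
```

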