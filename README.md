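# growthfx

Predicting directed growth effects between cocultured bacteria from their
phylogeny, their monoculture growth, and their interactions with other
species.

## What it does

Pairwise interactions shape what microbial communities do, but measuring all
of them scales quadratically in the number of species. `growthfx` implements
the analysis pipeline for droplet-screen data in which every species of a
panel is grown alone and in pairwise coculture across many carbon
environments. The central statistic is the one-way effect of species B on
species A in environment c,

    E(A <- B, c) = log( mean coculture yield of A with B in c
                        / mean monoculture yield of A in c ),

negative for inhibition, positive for facilitation. The package covers:

- **Dataset construction** — replicate filtering (< 3 replicates dropped by
  default), effect computation, two-way interaction typing (competition /
  mutualism / parasitism), CSV and newick I/O.
- **Synthetic screens** — a tested generator emulating the statistical
  structure of such screens (two clades, phylogenetically correlated
  monoculture yields, mostly negative effects that deepen with the affected
  species' monoculture yield, clade-conserved interaction profiles, weakly
  coupled reciprocal effects, missing combinations), so the whole pipeline
  runs end-to-end without any download.
- **Features** — monoculture yields of both partners, metabolic
  (profile-Euclidean) distance, 2 phylogenetic PCs per species, 4 carbon
  metabolic-profile PCs with out-of-sample projection for held-out
  environments; optional one-hot carbons, chemistry and pathway blocks, and
  the reciprocal effect.
- **Models** — one fitting entry point (`tune_and_train()`) over
  gradient-boosted trees, random forests, k-NN and linear/logistic families
  (seeded random hyperparameter search with 5-fold CV: MCC for sign, RMSE
  for strength), plus null, single-feature threshold, phylogenetic-copy and
  metabolic-copy baselines, and joint two-way (multilabel) prediction.
- **Evaluation** — stratified 80/20 splits, MCC/accuracy/precision/recall/
  ROC-AUC for sign, R² and NRMSE (RMSE / population SD of the test effects)
  for strength, error-vs-strength profiles, and leave-one-species /
  leave-one-carbon ablations over feature tiers with leakage guards.
- **Interpretation** — model-agnostic Shapley attributions (exact or
  sampling, exact local accuracy), copy-model error vs phylogenetic
  distance, and the maximal information coefficient (MIC) of reciprocal
  effects, implemented in compiled code with an exhaustive-grid oracle mode.

## Worked example

```r
library(growthfx)

cfg <- synthetic_config(seed = 42)   # the default screen conditions
cfg
#> synthetic_config: 20 species / 2 clades x 40 carbons x 3 reps
#>   effect model: beta_affected=-0.50 beta_affecting=0.15 conservation_sd=0.30 noise_sd=0.30
#>   target negative fraction 0.76, missing 7%, replicate CV 0.10, seed 42

screen <- simulate_dataset(cfg)      # tree -> yields -> replicate droplets -> effects
screen$dataset
#> interaction_dataset: 14136 directed effects, 20 species, 40 carbons
#>   negative fraction: 0.757  effect range: [-2.902, 2.149]

ft  <- assemble_features(screen$dataset)
sp  <- split_train_test(ft, test_frac = 0.2, seed = 42)

fit <- tune_and_train(model_spec("gradient_boosted_trees", "sign",
                                 budget = 10, seed = 42), sp$train)
classification_metrics(sp$test$sign,
                       predict(fit, sp$test),
                       predict(fit, sp$test, type = "score"))
#> sign metrics (n=2828): accuracy 0.834  MCC 0.514  precision 0.715  recall 0.527
#>   TP=362 FP=144 TN=1997 FN=325  TNR 0.933  NPV 0.860  AUC 0.882

rfit <- tune_and_train(model_spec("gradient_boosted_trees", "strength",
                                  budget = 10, seed = 42), sp$train)
regression_metrics(sp$test$effect, predict(rfit, sp$test))
#> strength metrics (n=2828): RMSE 0.403  NRMSE 0.598  R2 0.642

reciprocal_dependence(screen$dataset$effects)
#> reciprocal effects: MIC 0.129 over 7068 pairs (Pearson r -0.339)
```

Reading the output: the classifier recovers effect signs well above the
75.7%-negative base rate (MCC 0.51, AUC 0.88); the regressor explains about
64% of effect-strength variance, with errors at ~0.6 of the spread a mean
predictor would leave (NRMSE 1 ≈ predicting the mean). The low MIC says one
direction of a pair tells you little about the reciprocal direction. With
the full 2,500-draw search budget (`budget = 2500`) the model metrics
improve a little further; the worked example uses a 10-draw search so it
runs in seconds.

For real data, replace the generator with
`build_dataset(read_growth_table("growth.csv"), "tree.nwk")` — a long-format
CSV (`species,partner,carbon,replicate,yield`, monocultures flagged by the
partner token `MONO`) and a phylogeny as newick or a square distance CSV.
`run_experiment(experiment_config(...))` orchestrates the full pipeline
(effects → features → training → metrics → ablations → attributions) into an
output directory with a resolved config for provenance.

## Package layout

- `R/` — dataset core, synthetic generator, features, models, evaluation,
  ablations, Shapley attribution, MIC, pipeline orchestration.
- `src/` — the MIC characteristic-matrix dynamic program (Rcpp).
- `tests/testthat/` — unit, property and end-to-end suites with independent
  oracles (brute-force metrics, exhaustive threshold/MIC search,
  eigendecomposition checks).
- `vignettes/interaction-prediction.Rmd` — the model, its assumptions, every
  tunable parameter, and the design decisions.
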