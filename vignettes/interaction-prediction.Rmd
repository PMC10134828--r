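---
title: "Predicting directed growth effects between cocultured bacteria"
author: "growthfx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting directed growth effects between cocultured bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthfx)
```

## The problem

High-throughput droplet screens can measure, for a panel of bacterial
species, the endpoint growth yield of every species alone (monoculture) and
in pairwise coculture, across a panel of carbon environments. The quantity
of interest is the *one-way effect* of species B on species A in carbon c:

$$E(A \leftarrow B, c) \;=\; \log \frac{\bar y_{A|B,c}}{\bar y_{A,c}}$$

the log ratio of A's mean coculture yield with B to A's mean monoculture
yield in the same environment. Negative effects mean inhibition, positive
ones facilitation; the ordered pair of reciprocal effects classifies a
two-way interaction as competition (−,−), mutualism (+,+) or parasitism
(mixed). `growthfx` implements the full analysis around this statistic:
computing effects from replicate-level data, building predictive features,
training and evaluating models of effect sign and strength, quantifying what
happens when monoculture or coculture information is missing, and
interpreting the fitted models.

Three conventions in the effect statistic are deliberately explicit, because
the quantity is often described loosely in the literature:

* **Log base.** Natural log. The base only rescales effects, and every
  downstream metric here (NRMSE, R², MCC, MIC) is scale-aware, so the
  choice is a convention, not a modelling decision.
* **Replicate aggregation.** Arithmetic means of yields are taken *before*
  the ratio. Monoculture and coculture droplets are unpaired, so per-replicate
  log ratios are not defined; the mean-then-ratio form is the natural
  estimator for unpaired designs.
* **Exact zeros.** `sign` is `"positive"` iff `effect > 0`; an exact zero is
  labelled negative. Exact zeros have measure zero on real fluorescence
  data, but a deterministic rule keeps synthetic edge cases reproducible.
  Flip the rule downstream if your convention differs.

Culture groups observed with fewer than three replicates are removed before
any effect is computed (`filter_min_replicates()`, threshold configurable),
and coculture records whose monoculture reference is missing or zero are
dropped with a warning rather than imputed with pseudo-counts: a missing
reference makes the ratio meaningless, and the replicate filter already
discards a few percent of combinations in screens of this type.

## The synthetic screen

Real screens of this design are rarely redistributable, so the package ships
a generator (`simulate_dataset()`) whose defaults emulate the statistical
structure such screens exhibit. It is first-class, tested code — every
downstream stage is exercised end-to-end against it — and it is
phenomenological by design: no consumer-resource or genome-scale metabolic
mechanism, only the observable statistical regularities.

The default configuration (`synthetic_config()`) encodes the study
conditions: 20 species from 2 clades, 40 carbon environments, 3 replicate
droplets per culture, a 76% negative-sign fraction, and 7% of pair × carbon
combinations missing. The moving parts:

* **Phylogeny.** One random coalescent tree per clade, rescaled to
  within-clade height 0.3, attached to a root at height 1, so between-clade
  patristic distances (2.0) dominate within-clade ones (≤ 0.6) — the
  two-taxonomic-group structure of such panels.
* **Monoculture yields.** Per carbon, species' latent log yields are drawn
  from a multivariate normal whose correlation decays with phylogenetic
  distance, scaled by `yield_phylo_corr` (default 0.7): related species have
  similar growth profiles. Yields are log-normal, hence non-negative with
  occasional near-zero non-growers.
* **Effects.** The latent effect of B on A in carbon c is
  `intercept + beta_affected * z(mono_A, c) + beta_affecting * z(mono_B, c)
  + u(A, clade(B), c) + eps`, where `z` is the per-carbon standardization of
  log monoculture yields (standardizing makes the betas comparable across
  carbons of very different absolute yield). `beta_affected` is negative
  (default −0.5): species that grow well alone have more to lose from a
  competitor. `beta_affecting` is small and positive (default 0.15). The
  `u` term (sd 0.3) is shared by all affecting species of one clade acting
  on a given species in a given carbon — conservation planted on the
  *affecting* side, i.e. who you are determines how you affect others,
  which is the premise the nearest-relative copy model tests. The design is
  switchable to affected-side conservation by exchanging the roles in
  `simulate_effects()`. `eps` (sd 0.3) is idiosyncratic.
* **Calibration.** The intercept is set by bisection so that the realized
  negative-sign fraction hits `target_negative_frac` (default 0.76) within
  ±0.05; a constant latent field (all variance parameters zero) makes the
  target unreachable, and the generator then warns and uses intercept 0.
* **Noise and missingness.** Replicate yields get multiplicative log-normal
  noise with CV `replicate_cv` (default 0.1, a typical droplet-fluorescence
  replicate spread); a uniform 7% of unordered pair × carbon combinations is
  deleted. Real missingness is structured (it tracks poorly growing
  combinations), but no structure is specified by the screens this emulates,
  so uniform deletion is the neutral choice.

There is no quantitative anchor for "how conserved" interaction profiles are
between relatives; `conservation_sd = 0.3` was chosen once so that the
conservation-dependent analyses (copy-model error vs distance) show a clear
planted trend at realistic noise, and is not tuned thereafter.

What the generator does *not* emulate — structured missingness, carbon
chemistry, batch effects, heavy-tailed measurement error, higher-order
interactions in multi-species contexts — bounds what green tests mean: they
show the pipeline recovers planted structure of the kind described above,
not that any particular real screen is predictable.

## Features

`assemble_features()` produces one row per directed effect with 11 mandatory
columns:

* `mono_affected`, `mono_affecting` — raw monoculture yields of both species
  in the focal carbon. Raw rather than log scale by default (`log_mono`
  toggles): tree models are invariant to monotone per-feature transforms,
  and raw yields keep the linear/kNN families' standardization meaningful.
  These per-row features are never imputed; rows lacking them are excluded,
  mirroring the screen's dropped combinations.
* `metab_dist` — Euclidean distance between the two species' monoculture
  yield profiles across all carbons.
* `phylo_pc1/2_affected/affecting` — each species' coordinates on the first
  two principal components of the phylogenetic distance matrix, treating
  each species' row of distances as its feature vector. This is plain PCA on
  the rows, not classical MDS/PCoA (no double centering); with clade
  structure the two capture essentially all variance either way, and the
  choice is documented as switchable.
* `carbon_pc1..4` — each environment's coordinates on the first four PCs of
  its *metabolic profile*, the vector of all species' monoculture yields in
  that carbon. The fitted center and loadings are retained so a held-out
  environment can be projected (`project_heldout_carbon()`) without
  refitting — the treatment a genuinely new environment would receive. The
  projection uses all species' rows of the profile; only the held-out
  environment's *pair* data are off limits, its monoculture profile is not.

For profile-based quantities (carbon PCs, metabolic distance) missing
monoculture entries are imputed by the species' mean yield across carbons —
a deliberate asymmetry with the never-imputed per-row features: profile
geometry degrades gracefully under mean imputation, a per-row yield does
not. Eigenvector signs are pinned (largest-magnitude loading positive) so
all PCA outputs are identical across runs and platforms. Optional blocks add
carbon one-hot indicators, user-supplied carbon chemistry descriptors, a
binary species × pathway matrix (always supplied, never inferred from
sequences), and the measured opposite-direction effect (`reciprocal_effect`).

## Models

`tune_and_train()` is the single fitting entry point; it returns an
`interaction_model` with `predict`, `print` and `summary` methods and a
schema check that refuses feature tables other than the ones it was trained
on. Families: gradient-boosted trees (xgboost; the two-way task uses its
multi-output trees), random forest (ranger), k-nearest neighbours, and
linear/logistic models, plus two naive baselines — a null model (training
majority sign / mean effect) and single-feature threshold rules.

Hyperparameters are selected by seeded random search with k-fold
cross-validation, scored by MCC for sign tasks and RMSE for strength, then
the winner is refit on the full training set. Search ranges (learning rate
0.03–0.3, depth 2–6, 40–200 rounds, subsampling 0.6–1, k ≤ 30, …) are
desk-scale defaults chosen for a ~10⁴-row screen and are fully overridable
via `model_spec(params = …)`; published range tables for specific studies
can be dropped in directly. The formal search budget defaults to 2,500
draws; the pipeline default is 50, which on data of this size recovers
nearly all of the attainable CV score at a fraction of the cost. Features
are standardized from training statistics for the linear and kNN families
only — tree ensembles are split-invariant and are left on the raw scale.

The threshold baseline scans every midpoint between consecutive distinct
feature values plus ±∞, and *both* inequality directions: whether, say,
large metabolic distance predicts inhibition is a hypothesis, not a given,
so the direction is learned. Ties go to the smaller threshold, then to the
"≥ maps to negative" direction, making the fit deterministic.

Copy models are dataset-level predictors rather than feature-table models:
`phylo_copy_predict()` answers queries about an uncultured species by
copying the record of its phylogenetically closest relative with the same
partner and carbon (distance ties broken lexicographically), and
`metabolic_copy_predict()` mirrors this over environments ranked by
metabolic-profile distance. When the nearest source lacks the needed record
the prediction falls back to the next closest — dropping such queries
instead would shrink every comparison's test set incomparably.

## Evaluation

Splits are uniform at the record level, 80/20 by default, and stratified by
sign: stratification stabilizes MCC on 3:1-imbalanced data. A plain random
split (`stratify = FALSE`) matches the literal random-split protocol, and a
pair-grouped option keeps both directions of a species pair on one side for
users worried about directed-pair leakage; the default deliberately allows
A→B in train with B→A in test, as record-level splits do.

NRMSE divides RMSE by the *population* (ddof = 0) standard deviation of the
observed test effects, so a mean predictor scores exactly 1 — the dashed
reference line in ablation figures. MCC handles the imbalance; ROC-AUC is
reported when a model yields scores (threshold and copy models do not).
`error_vs_strength_profile()` bins false positives and negatives by true
effect strength, showing whether a classifier errs mostly near zero.

The two leave-one-out harnesses quantify partial information. Holding out a
species: the `full` tier is the global model evaluated on the held-out
species' share of the global test set; `no_coculture` retrains without any
of its interactions (monoculture features intact); `no_coculture_no_monoculture`
additionally drops `mono_*` and `metab_dist` from train and test;
`phylo_only` keeps just the four phylogenetic PCs; `copy` and `null`
complete the comparison. The carbon axis mirrors this with the metabolic
copy model, and the held-out environment's carbon PCs always come from
projection onto a PCA fitted without it. A leakage guard asserts that no
training row references the held-out unit. Hyperparameters are selected once
on the global split and reused across the per-unit refits (`retune = TRUE`
re-searches per unit at k× the cost); per-unit re-tuning changes medians
negligibly on data of this scale.

## Interpretation

`attribute_predictions()` computes Shapley attributions with a
marginal-expectation value function: the payoff of a feature coalition is
the mean model output over a background sample (default 100 seeded training
rows) with the coalition's features set to the explained row's values. Exact
enumeration is available up to 12 features; above that, seeded permutation
sampling is used. Both modes satisfy local accuracy *exactly* — the
permutation walk telescopes — so the base value plus a row's attributions
always reproduces its prediction, and a tolerance check enforces this. The
sampling construction is model-agnostic on purpose: it needs only a predict
function, not tree internals, so every family (including the naive ones with
scores) is attributable with the same estimator. Path-dependent tree-specific
attribution and pairwise interaction values are out of scope.

`copy_accuracy_vs_distance()` scores, for every ordered (target, source)
species pair, how well the source's records predict the target's, and
correlates that error with phylogenetic distance — the direct test of
interaction conservation.

`reciprocal_dependence()` measures how informative one direction of a pair
is about the other using the maximal information coefficient: the maximum,
over all grid partitions with at most B(n) = n^0.6 cells, of the grid's
mutual information normalized by log of the smaller grid dimension. The
implementation follows the characteristic-matrix algorithm — equipartition
one axis, optimize the other axis' cut points by dynamic programming over
clump boundaries (at most 15 × columns clumps), in both orientations — in
compiled code, with B(n) floored at 4 so the 2×2 grid is always admissible.
It is rank-based and therefore invariant to monotone transforms, and
deterministic. An exhaustive-enumeration mode exists for n ≤ 12 and serves
as the oracle in the test suite.

## Problem sizes and numerical choices

The package's tests and examples run the default 20 × 40 screen (~14,000
directed effects); seed-swept property checks use ten replicate screens, a
tuning budget of 50, eight-permutation attributions of 60 test rows, and
five held-out units per axis and seed in the ablation sweeps. These sizes
were chosen as the smallest at which the planted signals are unambiguous;
all of them scale up by changing one argument. Other numerical conventions:
PCA sign pinning (above); effect ties at zero labelled negative; bisection
tolerance ±0.05 on the sign-fraction calibration; Shapley local-accuracy
tolerance 1e-6; copy-model ties broken lexicographically; all randomness
fanned out from one seed via a fixed counter scheme (`stage_seed()`), so any
stage can be re-run in isolation.

## Limitations

Everything quantitative shown by the test suite is a statement about the
generator's planted structure, not about any real screen. The feature set
assumes monoculture yields are measured on a comparable scale across
carbons; systematic batch effects between environments would leak into both
the carbon PCs and the mono features. The copy models require at least one
usable source record and will fall back silently to more distant sources as
data thin out. MIC values at small n (< a few hundred pairs) carry
noticeable positive bias, as all maximal-dependence statistics do; compare
against a shuffled-pair baseline when in doubt.
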