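# Memoized default-condition screens (20 species x 40 carbons) for the
# seed-swept property tests, so several tests can share one generation.
.sweep_cache <- new.env(parent = emptyenv())

default_screen <- function(seed, ...) {
  key <- paste0("s", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.sweep_cache[[key]]))
    .sweep_cache[[key]] <- simulate_dataset(synthetic_config(seed = seed, ...))
  .sweep_cache[[key]]
}

# Fixed desk-scale gradient-boosting configuration reused wherever the
# hyperparameter search itself is not under test.
pinned_gbt <- function(task = "strength", seed = 1)
  model_spec("gradient_boosted_trees", task, budget = 1, seed = seed,
             params = list(eta = 0.1, max_depth = 4, nrounds = 80, subsample = 1,
                           colsample_bytree = 1, min_child_weight = 1, lambda = 1))
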