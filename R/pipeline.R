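# End-to-end orchestration: generate or load a dataset, build features, train
# and evaluate sign/strength models with their naive baselines, optionally run
# ablations, two-way comparison, attribution and the reciprocal-effect MIC,
# writing every table to the output directory with a resolved config for
# provenance.

#' Configure an end-to-end experiment
#'
#' @param out_dir Output directory (created; all result tables land here).
#' @param synthetic A [synthetic_config()] used when no input files are given
#'   (its seed is overridden by the experiment seed).
#' @param growth_csv,phylo Optional paths to a replicate-level growth CSV and
#'   a phylogeny (square CSV or newick); when set, they replace the synthetic
#'   generator.
#' @param tasks Character subset of `c("sign", "strength")`.
#' @param family ML family for the main models.
#' @param budget,cv_folds Tuning draws and CV folds (defaults 50 and 5 — a
#'   desk-scale search; raise `budget` for exhaustive tuning).
#' @param test_frac Test fraction for the global split.
#' @param ablation_axes Subset of `c("species", "carbon")` to run LOO
#'   ablations over (default none).
#' @param two_way Also run the two-way (multilabel vs twice-one-way)
#'   strength comparison.
#' @param attribution Attribute the strength model's test predictions.
#' @param attribution_rows Number of leading test rows to attribute
#'   (default 100; attribution cost scales linearly in rows).
#' @param reciprocal_mic Compute the MIC between reciprocal effects.
#' @param copy_distance Run the copy-accuracy-vs-distance analysis.
#' @param min_reps Replicate filter threshold.
#' @param seed Global seed; fans out to stage seeds via [stage_seed()].
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(out_dir, synthetic = synthetic_config(),
                              growth_csv = NULL, phylo = NULL,
                              tasks = c("sign", "strength"),
                              family = "gradient_boosted_trees",
                              budget = 50, cv_folds = 5, test_frac = 0.2,
                              ablation_axes = character(0), two_way = FALSE,
                              attribution = TRUE, attribution_rows = 100,
                              reciprocal_mic = TRUE,
                              copy_distance = TRUE, min_reps = 3, seed = 1) {
  stopifnot(all(tasks %in% c("sign", "strength")))
  structure(list(out_dir = out_dir, synthetic = synthetic,
                 growth_csv = growth_csv, phylo = phylo, tasks = tasks,
                 family = family, budget = budget, cv_folds = cv_folds,
                 test_frac = test_frac, ablation_axes = ablation_axes,
                 two_way = two_way, attribution = attribution,
                 attribution_rows = attribution_rows,
                 reciprocal_mic = reciprocal_mic, copy_distance = copy_distance,
                 min_reps = min_reps, seed = as.integer(seed)),
            class = "experiment_config")
}

config_to_yaml <- function(config, path) {
  plain <- rapply(unclass(config), f = function(x) x, how = "replace")
  plain$synthetic <- unclass(plain$synthetic)
  yaml::write_yaml(plain, path)
}

#' Read an experiment config from YAML
#' @param path YAML file with the fields of [experiment_config()].
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) do.call(synthetic_config, y$synthetic)
         else synthetic_config()
  y$synthetic <- syn
  do.call(experiment_config, y)
}

#' Compare joint two-way prediction with twice-applied one-way prediction
#'
#' Arranges the data per unordered pair and carbon, with the feature row of
#' one fixed direction and both directed effects as labels; fits (i) a
#' multilabel model predicting the effect pair jointly and (ii) two
#' independent single-output models, and evaluates both by NRMSE pooled over
#' the two outputs of the same test split.
#'
#' @param dataset An `interaction_dataset`.
#' @param spec A strength-task [model_spec()] (its family/tuning setup is
#'   reused for both approaches; the joint model runs as task `two_way`).
#' @param test_frac,seed Split parameters.
#' @return List of class `two_way_comparison`: `nrmse_two_way`,
#'   `nrmse_one_way`, `n_test`, and both fitted models.
#' @export
two_way_comparison <- function(dataset, spec, test_frac = 0.2, seed = 1) {
  ft <- assemble_features(dataset)
  key <- paste(ft$affected, ft$affecting, ft$carbon, sep = "\r")
  mirror <- paste(ft$affecting, ft$affected, ft$carbon, sep = "\r")
  m <- match(mirror, key)
  keep <- ft$affected < ft$affecting & !is.na(m)
  pair_ft <- ft[keep, , drop = FALSE]
  attr(pair_ft, "feature_cols") <- feature_columns(ft)
  class(pair_ft) <- class(ft)
  y <- cbind(effect_ab = pair_ft$effect, effect_ba = ft$effect[m[keep]])
  sp <- split_train_test(cbind(pair_ft, .row = seq_len(nrow(pair_ft))),
                         test_frac, seed = seed, stratify = FALSE)
  tr <- sp$train$.row; te <- sp$test$.row
  Xcols <- feature_columns(ft)
  trf <- pair_ft[tr, , drop = FALSE]; tef <- pair_ft[te, , drop = FALSE]
  for (d in c("trf", "tef")) {
    v <- get(d); attr(v, "feature_cols") <- Xcols; class(v) <- class(ft); assign(d, v)
  }
  spec2 <- spec; spec2$task <- "two_way"
  m_joint <- tune_and_train(spec2, trf, y[tr, ])
  spec1 <- spec; spec1$task <- "strength"
  m_ab <- tune_and_train(spec1, trf, y[tr, 1])
  m_ba <- tune_and_train(spec1, trf, y[tr, 2])
  p_joint <- predict(m_joint, tef)
  p_one <- cbind(predict(m_ab, tef), predict(m_ba, tef))
  nr <- function(pred) regression_metrics(as.vector(y[te, ]), as.vector(pred))$nrmse
  structure(list(nrmse_two_way = nr(p_joint), nrmse_one_way = nr(p_one),
                 n_test = length(te) * 2L,
                 model_two_way = m_joint, models_one_way = list(m_ab, m_ba)),
            class = "two_way_comparison")
}

#' @export
print.two_way_comparison <- function(x, ...) {
  cat(sprintf("two-way prediction: joint NRMSE %.3f vs twice-one-way NRMSE %.3f (n=%d)\n",
              x$nrmse_two_way, x$nrmse_one_way, x$n_test))
  invisible(x)
}

#' Run a configured experiment end to end
#'
#' Stages: dataset (synthetic or loaded) -> effects CSV -> feature CSV ->
#' global split -> model training with null/threshold baselines -> metrics
#' CSV -> optional two-way comparison, LOO ablations, attribution table,
#' reciprocal MIC and copy-distance analysis. Deterministic given the config
#' seed; any stage error aborts with a stage-tagged message.
#'
#' @param config An [experiment_config()] or path to its YAML serialization.
#' @return Invisibly, a list with the dataset, fitted models, metric tables
#'   and output paths.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out, "run.log")
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", file = logfile, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    log_line("stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  config_to_yaml(config, file.path(out, "config.yaml"))

  ds <- stage("dataset", {
    if (!is.null(config$growth_csv)) {
      build_dataset(read_growth_table(config$growth_csv), config$phylo,
                    min_reps = config$min_reps)
    } else {
      syn <- config$synthetic
      syn$seed <- stage_seed(config$seed, 1)
      simulate_dataset(syn, min_reps = config$min_reps)$dataset
    }
  })
  stage("effects", write_effects(ds$effects, file.path(out, "effects.csv")))
  ft <- stage("features", {
    f <- assemble_features(ds)
    write_features(f, file.path(out, "features.csv"))
    f
  })
  sp <- stage("split", split_train_test(ft, config$test_frac,
                                        seed = stage_seed(config$seed, 2)))
  metrics <- list()
  add_metric <- function(task, model, report) {
    for (nm in setdiff(names(report), c("task", "n", "tp", "fp", "tn", "fn")))
      metrics[[length(metrics) + 1L]] <<- data.frame(
        task = task, model = model, metric = nm,
        value = as.numeric(report[[nm]]), n = report$n, stringsAsFactors = FALSE)
  }
  models <- list()
  for (task in config$tasks) {
    stage(paste0("train_", task), {
      spec <- model_spec(config$family, task, budget = config$budget,
                         cv_folds = config$cv_folds,
                         seed = stage_seed(config$seed, 3))
      fit <- tune_and_train(spec, sp$train)
      models[[task]] <- fit
      if (task == "sign") {
        pred <- predict(fit, sp$test)
        scores <- tryCatch(predict(fit, sp$test, type = "score"),
                           error = function(e) NULL)
        add_metric(task, config$family,
                   classification_metrics(sp$test$sign, pred, scores))
        null_fit <- tune_and_train(model_spec("null", "sign"), sp$train)
        add_metric(task, "null",
                   classification_metrics(sp$test$sign, predict(null_fit, sp$test)))
        for (feat in intersect(c("metab_dist", "mono_affected"), feature_columns(ft))) {
          th <- fit_threshold_model(feat, sp$train)
          add_metric(task, paste0("threshold_", feat),
                     classification_metrics(sp$test$sign, predict(th, sp$test)))
        }
      } else {
        pred <- predict(fit, sp$test)
        add_metric(task, config$family, regression_metrics(sp$test$effect, pred))
        null_fit <- tune_and_train(model_spec("null", "strength"), sp$train)
        add_metric(task, "null",
                   regression_metrics(sp$test$effect, predict(null_fit, sp$test)))
      }
    })
  }
  results <- list(dataset = ds, features = ft, split = sp, models = models)
  if (config$two_way) {
    tw <- stage("two_way", two_way_comparison(
      ds, model_spec(config$family, "strength", budget = config$budget,
                     cv_folds = config$cv_folds, seed = stage_seed(config$seed, 4)),
      test_frac = config$test_frac, seed = stage_seed(config$seed, 5)))
    metrics[[length(metrics) + 1L]] <- data.frame(
      task = "two_way", model = "multilabel", metric = "nrmse",
      value = tw$nrmse_two_way, n = tw$n_test, stringsAsFactors = FALSE)
    metrics[[length(metrics) + 1L]] <- data.frame(
      task = "two_way", model = "one_way_twice", metric = "nrmse",
      value = tw$nrmse_one_way, n = tw$n_test, stringsAsFactors = FALSE)
    results$two_way <- tw
  }
  for (axis in config$ablation_axes) {
    ab <- stage(paste0("ablate_", axis), {
      specs <- lapply(config$tasks, function(task)
        model_spec(config$family, task, budget = config$budget,
                   cv_folds = config$cv_folds, seed = stage_seed(config$seed, 6)))
      fun <- if (axis == "species") loo_species_ablation else loo_carbon_ablation
      fun(ds, specs, split_seed = stage_seed(config$seed, 7))
    })
    write_csv_precise(as.data.frame(ab), file.path(out, paste0("ablation_", axis, ".csv")))
    results[[paste0("ablation_", axis)]] <- ab
  }
  if (config$attribution && "strength" %in% config$tasks) {
    nat <- min(config$attribution_rows %||% 100, nrow(sp$test))
    at <- stage("attribution", attribute_predictions(
      models$strength, sp$test[seq_len(nat), , drop = FALSE],
      background = sp$train, method = "sampling", n_permutations = 10,
      seed = stage_seed(config$seed, 8)))
    write_attributions(at, file.path(out, "attributions.csv"))
    results$attribution <- at
  }
  if (config$reciprocal_mic) {
    rd <- stage("reciprocal_mic", reciprocal_dependence(ds$effects))
    metrics[[length(metrics) + 1L]] <- data.frame(
      task = "interpretation", model = "reciprocal_effects", metric = "mic",
      value = rd$mic, n = rd$n_pairs, stringsAsFactors = FALSE)
    results$reciprocal <- rd
  }
  if (config$copy_distance) {
    cd <- stage("copy_distance", copy_accuracy_vs_distance(ds))
    write_csv_precise(cd$table, file.path(out, "copy_distance.csv"))
    metrics[[length(metrics) + 1L]] <- data.frame(
      task = "interpretation", model = "phylo_copy", metric = "pearson_r_error_distance",
      value = cd$pearson_r, n = nrow(cd$table), stringsAsFactors = FALSE)
    results$copy_distance <- cd
  }
  metrics_df <- do.call(rbind, metrics)
  metrics_df <- rbind(metrics_df, data.frame(
    task = "dataset", model = "observed", metric = "negative_fraction",
    value = mean(ds$effects$sign == "negative"), n = nrow(ds$effects),
    stringsAsFactors = FALSE))
  write_csv_precise(metrics_df, file.path(out, "metrics.csv"))
  results$metrics <- metrics_df
  log_line("done: %d metric rows written", nrow(metrics_df))
  invisible(results)
}
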