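# Partial-information ablations: how well are interactions predicted for an
# uncultured species (no coculture data, optionally no monoculture data) or an
# unobserved carbon environment. Feature tiers per held-out unit:
#   full       — global model (random 80/20 over all records), evaluated on
#                the held-out unit's share of the global test set
#   no_coculture                — unit's records removed from training
#   no_coculture_no_monoculture — additionally drops mono/metabolic-distance
#                                 features from train and test
#   phylo_only — only the phylogenetic PCs
#   copy       — phylogenetic (species axis) / metabolic (carbon axis) copy
#   null       — train-mean / majority-sign reference

MONO_COLS <- c("mono_affected", "mono_affecting", "metab_dist")

subset_cols <- function(ft, keep) {
  out <- ft
  attr(out, "feature_cols") <- intersect(feature_columns(ft), keep)
  out
}

ablation_metric <- function(task, y_true, y_pred) {
  if (task == "sign") mcc(y_true, y_pred)
  else regression_metrics(y_true, y_pred)$nrmse
}

metric_name <- function(task) if (task == "sign") "mcc" else "nrmse"

# Pin a spec's hyperparameters to a previously selected configuration so the
# per-unit refits reuse the global winners.
pin_spec <- function(spec, model) {
  hp <- model$search$hyperparameters
  if (length(hp)) spec$params <- hp
  spec
}

run_loo_axis <- function(dataset, specs, units, axis, retune = FALSE,
                         split_seed = 1) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  res <- list()
  ft_full <- assemble_features(dataset)
  for (spec in specs) {
    task <- spec$task
    labels_of <- function(ft) if (task == "sign") ft$sign else ft$effect
    sp_global <- split_train_test(ft_full, 0.2, seed = split_seed,
                                  stratify = task == "sign")
    global_model <- tune_and_train(spec, sp_global$train)
    fit_spec <- if (retune) spec else pin_spec(spec, global_model)
    for (u in units) {
      involves <- if (axis == "species")
        ft_full$affected == u | ft_full$affecting == u
      else ft_full$carbon == u
      if (!any(involves)) {
        warning("no records for held-out ", axis, " ", u, "; skipped")
        next
      }
      # carbon axis: refit feature table with held-out-environment projection
      ft <- if (axis == "carbon")
        assemble_features(dataset, feature_options(exclude_carbon_from_pca = u))
      else ft_full
      inv <- if (axis == "species") ft$affected == u | ft$affecting == u
             else ft$carbon == u
      train <- ft[!inv, , drop = FALSE]
      test <- ft[inv, , drop = FALSE]
      leak <- if (axis == "species") train$affected == u | train$affecting == u
              else train$carbon == u
      if (any(leak)) stop("leakage: training rows reference held-out unit")
      attr(train, "feature_cols") <- attr(test, "feature_cols") <- feature_columns(ft)
      class(train) <- class(test) <- class(ft)
      add <- function(variant, value, n) {
        res[[length(res) + 1L]] <<- data.frame(
          axis = axis, held_out_id = u, variant = variant, task = task,
          metric = metric_name(task), value = value, n_test = n,
          stringsAsFactors = FALSE)
      }
      y_te <- labels_of(test)
      # full: global model on this unit's share of the global test set
      gte <- sp_global$test
      ginv <- if (axis == "species") gte$affected == u | gte$affecting == u
              else gte$carbon == u
      if (sum(ginv) >= 2 && (task != "sign" || length(unique(gte$sign[ginv])) >= 1)) {
        pr <- predict(global_model, gte[ginv, , drop = FALSE])
        add("full", ablation_metric(task, labels_of(gte)[ginv], pr), sum(ginv))
      }
      variants <- list(
        no_coculture = feature_columns(ft),
        no_coculture_no_monoculture = setdiff(feature_columns(ft), MONO_COLS),
        phylo_only = grep("^phylo_pc", feature_columns(ft), value = TRUE))
      for (vn in names(variants)) {
        tr_v <- subset_cols(train, variants[[vn]])
        te_v <- subset_cols(test, variants[[vn]])
        m <- tune_and_train(fit_spec, tr_v)
        add(vn, ablation_metric(task, y_te, predict(m, te_v)), nrow(test))
      }
      # copy baseline
      copy_pred <- tryCatch({
        if (axis == "species")
          phylo_copy_predict(dataset, test, excluded_species = u,
                             task = if (task == "sign") "sign" else "strength")
        else
          metabolic_copy_predict(dataset, test, excluded_carbon = u,
                                 task = if (task == "sign") "sign" else "strength")
      }, error = function(e) NULL)
      if (!is.null(copy_pred))
        add("copy", ablation_metric(task, y_te, as.vector(copy_pred)), nrow(test))
      # null reference from the no-coculture training set
      null_m <- tune_and_train(model_spec("null", task, seed = spec$seed), train)
      add("null", ablation_metric(task, y_te, predict(null_m, test)), nrow(test))
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("ablation_result", "data.frame")
  out
}

#' Leave-one-species-out ablation
#'
#' For each species, removes all its interactions from training, fits the
#' feature-tier models, and evaluates them on the held-out species'
#' interactions (NRMSE for strength tasks, MCC for sign tasks), alongside the
#' phylogenetic-copy and null baselines. Hyperparameters are selected once on
#' a global split and reused for every refit unless `retune = TRUE`.
#'
#' @param dataset An `interaction_dataset`.
#' @param specs A [model_spec()] or list of them (one per task).
#' @param species_list Species to hold out (default: all).
#' @param retune Re-run the hyperparameter search per held-out unit.
#' @param split_seed Seed for the global 80/20 split behind the `full` tier.
#' @return An `ablation_result` data.frame: one row per
#'   (held_out_id, variant, task) with the test metric and test size.
#' @export
loo_species_ablation <- function(dataset, specs, species_list = NULL,
                                 retune = FALSE, split_seed = 1) {
  species_list <- species_list %||% rownames(dataset$phylo_dist)
  run_loo_axis(dataset, specs, species_list, "species", retune, split_seed)
}

#' Leave-one-carbon-out ablation
#'
#' Mirror of [loo_species_ablation()] over carbon environments: the held-out
#' environment's records leave the training set, its carbon-PC features come
#' from projecting its monoculture profile onto a PCA fitted on the remaining
#' environments, and the metabolic-copy model is the copy baseline.
#'
#' @inheritParams loo_species_ablation
#' @param carbon_list Carbons to hold out (default: all).
#' @return An `ablation_result` data.frame.
#' @export
loo_carbon_ablation <- function(dataset, specs, carbon_list = NULL,
                                retune = FALSE, split_seed = 1) {
  carbon_list <- carbon_list %||% sort(unique(dataset$effects$carbon))
  run_loo_axis(dataset, specs, carbon_list, "carbon", retune, split_seed)
}

#' @export
print.ablation_result <- function(x, ...) {
  agg <- stats::aggregate(value ~ axis + task + variant, data = x, FUN = stats::median)
  cat("ablation_result:", nrow(x), "rows; median metric per variant:\n")
  print(format(agg, digits = 3), row.names = FALSE)
  invisible(x)
}
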