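# The uniform model layer: tuning, prediction contracts, naive baselines.

fast_gbt <- function(task, seed = 1)
  model_spec("gradient_boosted_trees", task, budget = 1, seed = seed,
             params = list(eta = 0.1, max_depth = 4, nrounds = 60, subsample = 1,
                           colsample_bytree = 1, min_child_weight = 1, lambda = 1))

test_that("null models reproduce training-set summaries and ignore features", {
  s <- small_screen()
  ft <- assemble_features(s$dataset)
  sp <- split_train_test(ft, 0.2, seed = 1)
  m_null_s <- tune_and_train(model_spec("null", "strength"), sp$train)
  expect_equal(unique(predict(m_null_s, sp$test)), mean(sp$train$effect))
  m_null_c <- tune_and_train(model_spec("null", "sign"), sp$train)
  expect_equal(unique(predict(m_null_c, sp$test)),
               names(which.max(table(sp$train$sign))))
  # permuting feature values changes nothing
  scram <- sp$test
  for (cl in feature_columns(ft)) scram[[cl]] <- sample(scram[[cl]])
  expect_identical(predict(m_null_s, scram), predict(m_null_s, sp$test))
})

test_that("budget one trains the single sampled configuration", {
  s <- small_screen()
  ft <- assemble_features(s$dataset)
  sp <- split_train_test(ft, 0.2, seed = 1)
  fit <- tune_and_train(fast_gbt("strength"), sp$train)
  expect_equal(fit$search$n_configs, 1L)
  expect_equal(fit$search$hyperparameters$nrounds, 60)
})

test_that("model training and prediction are reproducible under a fixed seed", {
  s <- small_screen()
  ft <- assemble_features(s$dataset)
  sp <- split_train_test(ft, 0.2, seed = 1)
  spec <- model_spec("gradient_boosted_trees", "strength", budget = 4, seed = 9)
  f1 <- tune_and_train(spec, sp$train)
  f2 <- tune_and_train(spec, sp$train)
  expect_identical(f1$search$hyperparameters, f2$search$hyperparameters)
  expect_identical(predict(f1, sp$test), predict(f2, sp$test))
})

test_that("prediction refuses mismatched feature schemas", {
  s <- small_screen()
  ft <- assemble_features(s$dataset)
  sp <- split_train_test(ft, 0.2, seed = 1)
  fit <- tune_and_train(fast_gbt("strength"), sp$train)
  X <- growthfx:::feature_matrix(sp$test)
  expect_error(predict(fit, X[, 1:5]), "schema")
  colnames(X)[1] <- "renamed"
  expect_error(predict(fit, X), "schema")
})

test_that("single-class sign training sets are rejected", {
  s <- small_screen()
  ft <- assemble_features(s$dataset)
  ft$sign <- "negative"
  expect_error(tune_and_train(model_spec("null", "sign"), ft), "degenerate labels")
})

test_that("every ML family fits and beats or matches the null model", {
  s <- small_screen()
  ft <- assemble_features(s$dataset)
  sp <- split_train_test(ft, 0.2, seed = 2)
  null_rmse <- regression_metrics(
    sp$test$effect,
    predict(tune_and_train(model_spec("null", "strength"), sp$train), sp$test))$rmse
  for (fam in c("gradient_boosted_trees", "random_forest",
                "k_nearest_neighbors", "linear")) {
    fit <- tune_and_train(model_spec(fam, "strength", budget = 3, seed = 1), sp$train)
    rmse <- regression_metrics(sp$test$effect, predict(fit, sp$test))$rmse
    expect_lte(rmse, null_rmse * 1.02)
    # sign task also runs and emits valid labels
    fitc <- tune_and_train(model_spec(fam, "sign", budget = 3, seed = 1), sp$train)
    expect_true(all(predict(fitc, sp$test) %in% c("positive", "negative")))
  }
})

test_that("a dominant configuration wins the cross-validated search", {
  s <- small_screen()
  ft <- assemble_features(s$dataset)
  sp <- split_train_test(ft, 0.2, seed = 1)
  # nrounds 2 vs 120 at modest eta: the larger model dominates every fold
  spec <- model_spec("gradient_boosted_trees", "strength", budget = 8, seed = 3,
                     params = list(eta = 0.1, max_depth = 4, nrounds = c(2L, 120L),
                                   subsample = 1, colsample_bytree = 1,
                                   min_child_weight = 1, lambda = 1))
  fit <- tune_and_train(spec, sp$train)
  expect_equal(fit$search$hyperparameters$nrounds, 120L)
})

test_that("threshold models recover separable rules and match brute force", {
  mk <- function(x, y) {
    X <- matrix(x, dimnames = list(NULL, "f"))
    fit_threshold_model("f", X, labels = y)
  }
  fit <- mk(c(1, 2, 3, 4), c("positive", "positive", "negative", "negative"))
  expect_equal(fit$backend$threshold, 2.5)
  expect_equal(fit$backend$accuracy, 1)
  expect_equal(fit$backend$label_ge, "negative")
  # all-negative labels: degenerate rule still reaches accuracy 1
  fit2 <- mk(c(1, 2, 3), rep("negative", 3))
  expect_equal(fit2$backend$accuracy, 1)
  # constant feature falls back to the majority sign with a warning
  expect_warning(fit3 <- mk(rep(2, 5), c("negative", "negative", "negative",
                                         "positive", "positive")), "constant")
  expect_equal(unique(predict(fit3, matrix(c(0, 9), dimnames = list(NULL, "f")))),
               "negative")
  # random instances: fitted accuracy equals exhaustive search
  set.seed(11)
  for (i in 1:25) {
    x <- round(rnorm(30), 1)
    y <- ifelse(runif(30) < 0.5, "negative", "positive")
    fit <- mk(x, y)
    expect_equal(fit$backend$accuracy, oracle_threshold_accuracy(x, y))
  }
})

test_that("two-way models predict both directions jointly and consistently", {
  s <- small_screen()
  tw <- two_way_comparison(s$dataset, fast_gbt("strength"), seed = 1)
  expect_true(is.finite(tw$nrmse_two_way) && is.finite(tw$nrmse_one_way))
  # joint prediction returns an aligned pair per row
  ft <- assemble_features(s$dataset)
  sp <- split_train_test(ft, 0.2, seed = 1)
  y2 <- cbind(sp$train$effect, -sp$train$effect + rnorm(nrow(sp$train), 0, 1e-6))
  spec <- fast_gbt("strength"); spec$task <- "two_way"
  fit <- tune_and_train(spec, sp$train, y2)
  pr <- predict(fit, sp$test)
  expect_equal(dim(pr), c(nrow(sp$test), 2))
  # the planted second output is the negation of the first
  expect_gt(cor(pr[, 1], -pr[, 2]), 0.95)
  # joint sign prediction
  ys <- cbind(sp$train$sign, ifelse(sp$train$effect > median(sp$train$effect),
                                    "positive", "negative"))
  fit_s <- tune_and_train(spec, sp$train, ys)
  prs <- predict(fit_s, sp$test)
  expect_equal(dim(prs), c(nrow(sp$test), 2))
  expect_true(all(prs %in% c("positive", "negative")))
})
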