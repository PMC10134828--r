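# Splits, metrics against independent oracles, and the error-strength profile.

test_that("splits are disjoint, exhaustive, and sized as requested", {
  rec <- data.frame(affected = rep(letters[1:5], 20), affecting = "z",
                    carbon = "c", effect = rnorm(100),
                    sign = rep(c("negative", "positive"), c(76, 24)))
  sp <- split_train_test(rec, 0.2, seed = 1, stratify = FALSE)
  expect_equal(nrow(sp$train), 80)
  expect_equal(nrow(sp$test), 20)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(rec))
  # stratified split preserves the class balance to within a couple records
  sps <- split_train_test(rec, 0.2, seed = 1, stratify = TRUE)
  expect_lte(abs(sum(sps$test$sign == "negative") - 0.76 * 20), 2)
  expect_error(split_train_test(rec, 1e-9), "empty")
})

test_that("pair-grouped splits keep both directions together", {
  s <- small_screen()
  eff <- s$dataset$effects
  sp <- split_train_test(eff, 0.25, seed = 2, group_pairs = TRUE)
  pair_of <- function(d) unique(paste(pmin(d$affected, d$affecting),
                                      pmax(d$affected, d$affecting)))
  expect_length(intersect(pair_of(sp$train), pair_of(sp$test)), 0)
})

test_that("classification metrics match an independent oracle", {
  # the worked confusion matrix: TP=8, FP=2, FN=2, TN=8
  y_true <- rep(c("positive", "negative"), each = 10)
  y_pred <- c(rep("positive", 8), rep("negative", 2),
              rep("positive", 2), rep("negative", 8))
  m <- classification_metrics(y_true, y_pred)
  expect_equal(m$mcc, 0.6)
  expect_equal(m$accuracy, 0.8)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(8, 2, 2, 8))
  # perfect predictions
  mp <- classification_metrics(y_true, y_true)
  expect_equal(mp$accuracy, 1); expect_equal(mp$mcc, 1)
  # balanced random confusion TP=TN=FP=FN=1 has no association
  m0 <- classification_metrics(c("positive", "positive", "negative", "negative"),
                               c("positive", "negative", "positive", "negative"))
  expect_equal(m0$mcc, 0)
  # random vectors against the oracle
  set.seed(7)
  for (i in 1:200) {
    yt <- sample(c("positive", "negative"), 40, replace = TRUE, prob = c(0.3, 0.7))
    yp <- sample(c("positive", "negative"), 40, replace = TRUE)
    got <- suppressWarnings(classification_metrics(yt, yp))
    want <- oracle_classification(yt, yp)
    expect_equal(got$mcc, unname(want$mcc))
    expect_equal(got$accuracy, unname(want$accuracy))
    expect_equal(c(got$tp, got$fp, got$tn, got$fn),
                 unname(c(want$tp, want$fp, want$tn, want$fn)))
  }
  expect_error(classification_metrics(y_true, y_pred[1:3]), "length")
})

test_that("ROC-AUC is produced from scores and ordered correctly", {
  y <- rep(c("negative", "positive"), each = 50)
  good <- c(rnorm(50, 0), rnorm(50, 3))
  m <- classification_metrics(y, ifelse(good > 1.5, "positive", "negative"), scores = good)
  expect_gt(m$auc, 0.9)
  perfect <- classification_metrics(y, y, scores = as.numeric(y == "positive"))
  expect_equal(perfect$auc, 1)
})

test_that("regression metrics implement population-SD NRMSE", {
  # perfect prediction
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$rmse, 0); expect_equal(m$nrmse, 0); expect_equal(m$r2, 1)
  # mean predictor identity: NRMSE exactly 1, R2 exactly 0
  y <- c(0.3, -1, 2, 0.7, -0.5)
  mm <- regression_metrics(y, rep(mean(y), 5))
  expect_equal(mm$nrmse, 1); expect_equal(mm$r2, 0)
  # hand arithmetic
  mh <- regression_metrics(c(0, 2), c(1, 1))
  expect_equal(mh$rmse, 1); expect_equal(mh$nrmse, 1)
  # oracle comparison on random vectors
  set.seed(8)
  for (i in 1:200) {
    yt <- rnorm(30); yp <- yt + rnorm(30, 0, 0.5)
    got <- regression_metrics(yt, yp); want <- oracle_regression(yt, yp)
    expect_equal(got$rmse, want$rmse)
    expect_equal(got$nrmse, want$nrmse)
    expect_equal(got$r2, want$r2)
  }
  expect_error(regression_metrics(c(1, 1), c(1, 2)), "degenerate test targets")
  expect_error(regression_metrics(1, 1), "two")
})

test_that("null strength models score NRMSE near 1 on in-distribution splits", {
  vals <- sapply(1:8, function(seed) {
    s <- small_screen(seed = seed)
    ft <- assemble_features(s$dataset)
    sp <- split_train_test(ft, 0.2, seed = seed)
    nullm <- tune_and_train(model_spec("null", "strength"), sp$train)
    regression_metrics(sp$test$effect, predict(nullm, sp$test))$nrmse
  })
  expect_true(all(vals > 0.9 & vals < 1.1))
})

test_that("error profiles place FP/FN counts in the right strength bins", {
  # no errors: all-zero histogram
  h0 <- error_vs_strength_profile(c(-1, 1), c("negative", "positive"),
                                  c("negative", "positive"), bins = 0.5)
  expect_true(all(h0$fp == 0) && all(h0$fn == 0))
  # a single false negative at strength -0.05 lands in [-0.1, 0)
  h1 <- error_vs_strength_profile(-0.05, "positive", "negative", bins = 0.1)
  row <- h1[h1$fn == 1, ]
  expect_equal(nrow(row), 1)
  expect_equal(c(row$bin_lo, row$bin_hi), c(-0.1, 0))
  # errors confined near zero leave distant bins empty; totals match
  set.seed(3)
  tr <- c(runif(50, -0.3, 0.3), runif(20, 1, 2), runif(20, -2, -1))
  ts <- ifelse(tr > 0, "positive", "negative")
  ps <- ts
  flip <- which(abs(tr) < 0.3)[1:10]
  ps[flip] <- ifelse(ts[flip] == "positive", "negative", "positive")
  h <- error_vs_strength_profile(tr, ts, ps, bins = 0.1)
  far <- h$bin_hi <= -0.5 | h$bin_lo >= 0.5
  expect_true(all(h$fp[far] == 0) && all(h$fn[far] == 0))
  expect_equal(sum(h$fp) + sum(h$fn), 10)
  expect_equal(sum(h$fp), sum(ts == "negative" & ps == "positive"))
})
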