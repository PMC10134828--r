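# Uniform model layer: one entry point (tune_and_train) over the ML families
# and the naive baselines, for three tasks:
#   sign     — binary classification (positive/negative effect)
#   strength — regression on the log-ratio effect
#   two_way  — joint prediction of both directed effects of a pair
# Hyperparameters are selected by seeded random search with k-fold CV (MCC for
# sign, RMSE for strength), then the winner is refit on the full training set.

ML_FAMILIES <- c("gradient_boosted_trees", "random_forest", "k_nearest_neighbors", "linear")
NAIVE_FAMILIES <- c("null", "threshold")

#' Specify a model family, task and tuning setup
#'
#' @param family One of `"gradient_boosted_trees"` (xgboost),
#'   `"random_forest"` (ranger), `"k_nearest_neighbors"`, `"linear"`
#'   (lm / logistic), `"null"` or `"threshold"`.
#' @param task `"sign"`, `"strength"` or `"two_way"`.
#' @param budget Random-search draws (default 2500; naive families ignore it).
#' @param cv_folds Cross-validation folds (default 5).
#' @param seed Integer seed controlling sampling, folds and stochastic fits.
#' @param params Named list overriding the default hyperparameter ranges:
#'   scalars pin a value, vectors give the candidate set. For
#'   `family = "threshold"`, `params$feature` names the thresholded feature.
#' @param standardize Standardize features from training statistics; default
#'   `TRUE` for linear and kNN families, `FALSE` otherwise.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = "gradient_boosted_trees",
                       task = c("sign", "strength", "two_way"),
                       budget = 2500, cv_folds = 5, seed = 1,
                       params = list(), standardize = NULL) {
  family <- match.arg(family, c(ML_FAMILIES, NAIVE_FAMILIES))
  task <- match.arg(task)
  stopifnot(budget >= 1, cv_folds >= 2)
  if (is.null(standardize))
    standardize <- family %in% c("linear", "k_nearest_neighbors")
  structure(list(family = family, task = task, budget = as.integer(budget),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 params = params, standardize = standardize),
            class = "model_spec")
}

# ---- label plumbing ---------------------------------------------------------

SIGN_LEVELS <- c("negative", "positive")

as_sign_factor <- function(y) {
  if (is.numeric(y)) y <- ifelse(y > 0, "positive", "negative")
  factor(as.character(y), levels = SIGN_LEVELS)
}

# Extract the feature matrix from a feature_table / data.frame / matrix.
feature_matrix <- function(features, schema = NULL) {
  if (inherits(features, "feature_table") && !is.null(feature_columns(features)))
    cols <- feature_columns(features)
  else if (is.data.frame(features))
    cols <- setdiff(names(features), c("affected", "affecting", "carbon", "effect", "sign"))
  else cols <- colnames(features)
  X <- as.matrix(as.data.frame(features)[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  if (!is.null(schema)) {
    if (!setequal(colnames(X), schema))
      stop("feature schema mismatch: model was trained on different columns")
    X <- X[, schema, drop = FALSE]
  }
  X
}

default_labels <- function(features, task) {
  if (!is.data.frame(features)) stop("labels must be supplied explicitly")
  if (task == "strength") features$effect else features$sign
}

# ---- hyperparameter spaces --------------------------------------------------

hyper_space <- function(family, p) {
  switch(family,
    gradient_boosted_trees = list(
      eta = c(0.03, 0.3), max_depth = 2:6, nrounds = c(40, 200),
      subsample = c(0.6, 1), colsample_bytree = c(0.6, 1),
      min_child_weight = 1:10, lambda = c(0, 2)),
    random_forest = list(
      num.trees = c(100, 500), mtry = seq_len(max(1, p)),
      min.node.size = 1:10),
    k_nearest_neighbors = list(k = 1:30),
    linear = list(),
    list())
}

sample_hyper <- function(spec, p) {
  space <- hyper_space(spec$family, p)
  for (nm in names(spec$params)) space[[nm]] <- spec$params[[nm]]
  if (length(space) == 0) return(list(list()))
  n <- if (all(lengths(space) == 1)) 1L else spec$budget
  with_seed(stage_seed(spec$seed, 11), {
    lapply(seq_len(n), function(i) {
      # integer vectors are discrete candidate sets; numeric length-2
      # vectors are uniform ranges; other vectors are sampled directly
      lapply(space, function(rng) {
        if (length(rng) == 1) rng
        else if (is.integer(rng)) sample(rng, 1)
        else if (is.double(rng) && length(rng) == 2)
          stats::runif(1, rng[1], rng[2])
        else sample(rng, 1)
      })
    })
  })
}

# ---- family backends --------------------------------------------------------

fit_backend <- function(family, task, X, y, hp, seed) {
  switch(family,
    gradient_boosted_trees = {
      nrounds <- as.integer(hp$nrounds %||% 100L)
      params <- list(tree_method = "hist", nthread = 1,
                     eta = hp$eta %||% 0.1, max_depth = hp$max_depth %||% 4,
                     subsample = hp$subsample %||% 1,
                     colsample_bytree = hp$colsample_bytree %||% 1,
                     min_child_weight = hp$min_child_weight %||% 1,
                     lambda = hp$lambda %||% 1, seed = seed)
      if (task == "sign") {
        params$objective <- "binary:logistic"
        lab <- as.numeric(as_sign_factor(y) == "positive")
        d <- xgboost::xgb.DMatrix(X, label = lab)
      } else if (task == "strength") {
        params$objective <- "reg:squarederror"
        d <- xgboost::xgb.DMatrix(X, label = as.numeric(y))
      } else {
        if (is.numeric(y)) {
          params$objective <- "reg:squarederror"
          params$multi_strategy <- "multi_output_tree"
          d <- xgboost::xgb.DMatrix(X, label = as.matrix(y))
        } else {
          cls <- joint_sign_class(y)
          params$objective <- "multi:softprob"
          params$num_class <- 4
          d <- xgboost::xgb.DMatrix(X, label = as.integer(cls) - 1L)
        }
      }
      list(kind = "xgb", fit = xgboost::xgb.train(params, d, nrounds = nrounds, verbose = 0))
    },
    random_forest = {
      if (task == "two_way") stop("random_forest does not support the two_way task")
      df <- data.frame(X, check.names = FALSE)
      if (task == "sign") {
        fit <- ranger::ranger(x = df, y = as_sign_factor(y), probability = TRUE,
                              num.trees = as.integer(hp$num.trees %||% 300),
                              mtry = min(hp$mtry %||% max(1, floor(sqrt(ncol(X)))), ncol(X)),
                              min.node.size = hp$min.node.size %||% 1,
                              seed = seed, num.threads = 1)
      } else {
        fit <- ranger::ranger(x = df, y = as.numeric(y),
                              num.trees = as.integer(hp$num.trees %||% 300),
                              mtry = min(hp$mtry %||% max(1, floor(ncol(X) / 3)), ncol(X)),
                              min.node.size = hp$min.node.size %||% 5,
                              seed = seed, num.threads = 1)
      }
      list(kind = "ranger", fit = fit)
    },
    k_nearest_neighbors = {
      y2 <- if (task == "sign") as_sign_factor(y)
            else if (task == "two_way" && !is.numeric(y)) joint_sign_class(y)
            else y
      list(kind = "knn", X = X, y = y2, k = as.integer(hp$k %||% 5), task = task)
    },
    linear = {
      df <- data.frame(X, check.names = TRUE)
      if (task == "sign") {
        fit <- stats::glm(as_sign_factor(y) ~ ., data = df, family = stats::binomial())
      } else if (task == "two_way" && !is.numeric(y)) {
        stop("linear family does not support joint two_way sign prediction")
      } else {
        fit <- stats::lm(as.matrix(y) ~ ., data = df)
      }
      list(kind = "linear", fit = fit, names = names(df))
    },
    stop("unknown ML family: ", family))
}

predict_backend <- function(backend, task, X) {
  switch(backend$kind,
    xgb = {
      p <- predict(backend$fit, xgboost::xgb.DMatrix(X))
      if (task == "sign") {
        list(label = ifelse(p > 0.5, "positive", "negative"), score = p)
      } else if (task == "strength") {
        list(value = p)
      } else if (is.matrix(p) && ncol(p) == 4) {
        lab <- joint_class_labels()[max.col(p)]
        list(label = split_joint_class(lab), score = p)
      } else list(value = p)
    },
    ranger = {
      pr <- predict(backend$fit, data.frame(X, check.names = FALSE), num.threads = 1)
      if (task == "sign") {
        sc <- pr$predictions[, "positive"]
        list(label = ifelse(sc > 0.5, "positive", "negative"), score = sc)
      } else list(value = pr$predictions)
    },
    knn = {
      if (task == "sign") {
        pr <- class::knn(backend$X, X, backend$y, k = backend$k, prob = TRUE)
        win <- attr(pr, "prob")
        sc <- ifelse(pr == "positive", win, 1 - win)
        list(label = as.character(pr), score = sc)
      } else if (task == "two_way" && is.factor(backend$y)) {
        pr <- class::knn(backend$X, X, backend$y, k = backend$k)
        list(label = split_joint_class(as.character(pr)))
      } else {
        # kNN regression (single or multi output) via caret's neighbor averaging
        y <- backend$y
        if (is.matrix(y) || is.data.frame(y)) {
          y <- as.matrix(y)
          out <- sapply(seq_len(ncol(y)), function(j)
            predict(caret::knnreg(backend$X, y[, j], k = backend$k), X))
          list(value = matrix(out, nrow = nrow(X)))
        } else {
          list(value = predict(caret::knnreg(backend$X, as.numeric(y), k = backend$k), X))
        }
      }
    },
    linear = {
      df <- data.frame(X, check.names = TRUE)
      names(df) <- backend$names
      if (inherits(backend$fit, "glm")) {
        sc <- predict(backend$fit, df, type = "response")
        list(label = ifelse(sc > 0.5, "positive", "negative"), score = unname(sc))
      } else {
        list(value = unname(predict(backend$fit, df)))
      }
    })
}

# joint sign-pair coding for the two_way sign task
joint_class_labels <- function() c("negative|negative", "negative|positive",
                                   "positive|negative", "positive|positive")
joint_sign_class <- function(y) {
  y <- as.matrix(y)
  factor(paste(y[, 1], y[, 2], sep = "|"), levels = joint_class_labels())
}
split_joint_class <- function(lab) {
  parts <- strsplit(lab, "|", fixed = TRUE)
  cbind(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2))
}

# ---- cross-validation scoring ----------------------------------------------

make_folds <- function(n, k, seed, strata = NULL) {
  with_seed(seed, {
    fold <- integer(n)
    if (is.null(strata)) {
      fold <- sample(rep(seq_len(k), length.out = n))
    } else {
      for (s in unique(strata)) {
        idx <- which(strata == s)
        fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
      }
    }
    fold
  })
}

cv_score <- function(spec, X, y, hp, fold) {
  scores <- vapply(seq_len(max(fold)), function(f) {
    tr <- fold != f
    backend <- fit_backend(spec$family, spec$task, X[tr, , drop = FALSE],
                           if (is.matrix(y)) y[tr, , drop = FALSE] else y[tr],
                           hp, stage_seed(spec$seed, 20 + f))
    pr <- predict_backend(backend, spec$task, X[!tr, , drop = FALSE])
    yte <- if (is.matrix(y)) y[!tr, , drop = FALSE] else y[!tr]
    if (spec$task == "sign") {
      mcc(as.character(as_sign_factor(yte)), pr$label)
    } else if (spec$task == "strength") {
      -sqrt(mean((as.numeric(yte) - pr$value)^2))
    } else if (is.numeric(y)) {
      -sqrt(mean((as.matrix(yte) - pr$value)^2))
    } else {
      mean(vapply(1:2, function(j) mcc(as.matrix(yte)[, j], pr$label[, j]), 0))
    }
  }, numeric(1))
  mean(scores)
}

# ---- the fitting entry point ------------------------------------------------

#' Tune and fit an interaction model
#'
#' Runs a seeded random hyperparameter search with k-fold cross-validation
#' (scored by MCC for sign tasks, RMSE for strength), refits the winning
#' configuration on the full training set, and returns a uniform model object.
#' Naive families skip the search.
#'
#' @param spec A [model_spec()].
#' @param features Training features: a `feature_table` or a numeric
#'   matrix/data.frame of feature columns.
#' @param labels Training labels; if `NULL` and `features` is a
#'   `feature_table`, taken from its `effect`/`sign` column per the task.
#'   For `two_way`, a two-column matrix (numeric effects or sign labels).
#' @return An object of class `interaction_model` with `predict`, `print` and
#'   `summary` methods.
#' @export
tune_and_train <- function(spec, features, labels = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  X <- feature_matrix(features)
  y <- labels %||% default_labels(features, spec$task)
  if (is.data.frame(y)) y <- as.matrix(y)
  n <- nrow(X)
  stopifnot((if (is.matrix(y)) nrow(y) else length(y)) == n)

  if (spec$task == "sign") {
    yf <- as_sign_factor(y)
    if (any(is.na(yf))) stop("sign labels must be positive/negative")
    if (length(unique(yf)) < 2) stop("degenerate labels: single-class sign training set")
    y <- as.character(yf)
  }
  train_summary <- list(
    majority_sign = if (spec$task == "sign") names(which.max(table(y)))
                    else if (spec$task == "two_way" && !is.numeric(y))
                      names(which.max(table(joint_sign_class(y)))),
    mean_effect = if (is.numeric(y)) {
      if (is.matrix(y)) colMeans(y) else mean(y)
    })

  std <- NULL
  if (spec$standardize && spec$family %in% ML_FAMILIES) {
    std <- list(center = colMeans(X), scale = apply(X, 2, stats::sd))
    std$scale[std$scale == 0] <- 1
    X <- scale(X, std$center, std$scale)
  }

  if (spec$family == "null") {
    model <- list(kind = "null")
    search <- NULL
  } else if (spec$family == "threshold") {
    return(fit_threshold_model(spec$params$feature %||% "metab_dist",
                               features, labels = y, spec = spec))
  } else {
    configs <- sample_hyper(spec, ncol(X))
    if (length(configs) > 1) {
      strata <- if (spec$task == "sign") y else NULL
      fold <- make_folds(n, spec$cv_folds, stage_seed(spec$seed, 10), strata)
      sc <- vapply(configs, function(hp) cv_score(spec, X, y, hp, fold), numeric(1))
      best <- which.max(sc)
      search <- list(n_configs = length(configs), cv_score = sc[best])
    } else {
      best <- 1L
      search <- list(n_configs = 1L, cv_score = NA_real_)
    }
    hp <- configs[[best]]
    model <- fit_backend(spec$family, spec$task, X, y, hp, stage_seed(spec$seed, 30))
    search$hyperparameters <- hp
  }
  structure(list(spec = spec, backend = model, schema = colnames(feature_matrix(features)),
                 standardize = std, search = search, train_summary = train_summary,
                 n_train = n),
            class = "interaction_model")
}

#' Predict from a fitted interaction model
#'
#' @param object An `interaction_model`.
#' @param newdata Feature table or matrix; must carry exactly the training
#'   feature columns (schema mismatch is an error).
#' @param type `"response"` (labels / strengths) or `"score"` (positive-class
#'   score for sign models that provide one).
#' @param ... Unused.
#' @return Character sign labels, numeric strengths, or a two-column object
#'   for two_way tasks.
#' @export
predict.interaction_model <- function(object, newdata, type = c("response", "score"), ...) {
  type <- match.arg(type)
  X <- feature_matrix(newdata, schema = object$schema)
  if (!is.null(object$standardize))
    X <- scale(X, object$standardize$center, object$standardize$scale)
  spec <- object$spec
  if (identical(object$backend$kind, "null")) {
    out <- switch(spec$task,
      sign = rep(object$train_summary$majority_sign, nrow(X)),
      strength = rep(object$train_summary$mean_effect, nrow(X)),
      two_way = if (!is.null(object$train_summary$majority_sign))
        split_joint_class(rep(object$train_summary$majority_sign, nrow(X)))
      else matrix(object$train_summary$mean_effect, nrow(X), 2, byrow = TRUE))
    if (type == "score") stop("null models provide no scores")
    return(out)
  }
  if (identical(object$backend$kind, "threshold")) {
    x <- X[, object$backend$feature]
    hit <- x >= object$backend$threshold
    lab <- ifelse(hit, object$backend$label_ge, object$backend$label_lt)
    if (type == "score") stop("threshold models provide no scores")
    return(lab)
  }
  pr <- predict_backend(object$backend, spec$task, X)
  if (type == "score") {
    if (is.null(pr$score)) stop("this model provides no scores")
    return(pr$score)
  }
  pr$label %||% pr$value
}

#' @export
print.interaction_model <- function(x, ...) {
  cat(sprintf("interaction_model: family=%s task=%s (n_train=%d)\n",
              x$spec$family, x$spec$task, x$n_train))
  if (!is.null(x$search$hyperparameters) && length(x$search$hyperparameters))
    cat("  selected:", paste(names(x$search$hyperparameters),
                             vapply(x$search$hyperparameters, function(v) format(v, digits = 3), ""),
                             sep = "=", collapse = " "), "\n")
  if (!is.null(x$search) && is.finite(x$search$cv_score %||% NA))
    cat(sprintf("  CV score (%s): %.4f over %d configurations\n",
                if (x$spec$task == "sign") "MCC" else "-RMSE",
                x$search$cv_score, x$search$n_configs))
  invisible(x)
}

#' @export
summary.interaction_model <- function(object, ...) {
  print(object)
  cat("  feature schema:", paste(object$schema, collapse = ", "), "\n")
  if (!is.null(object$train_summary$majority_sign))
    cat("  training majority sign:", object$train_summary$majority_sign, "\n")
  if (!is.null(object$train_summary$mean_effect))
    cat("  training mean effect:",
        paste(format(object$train_summary$mean_effect, digits = 4), collapse = ", "), "\n")
  invisible(object)
}

#' Fit a single-feature threshold model for effect sign
#'
#' Scans all candidate thresholds (midpoints between consecutive distinct
#' feature values, plus minus/plus infinity) and both inequality directions,
#' choosing the combination maximizing training accuracy. Ties are broken by
#' the smaller threshold, then by the direction mapping "feature >= threshold"
#' to a negative prediction.
#'
#' @param feature_name Feature to threshold (e.g. `"metab_dist"` or
#'   `"mono_affected"`).
#' @param train Training feature table (or matrix including the feature).
#' @param labels Binary sign labels; defaults to the table's `sign` column.
#' @param spec Optional [model_spec()] carried into the result.
#' @return An `interaction_model` (family `"threshold"`); for a constant
#'   feature, falls back to null-sign behaviour with a warning.
#' @export
fit_threshold_model <- function(feature_name, train, labels = NULL, spec = NULL) {
  X <- feature_matrix(train)
  if (!feature_name %in% colnames(X)) stop("unknown feature: ", feature_name)
  y <- as.character(as_sign_factor(labels %||% default_labels(train, "sign")))
  x <- X[, feature_name]
  spec <- spec %||% model_spec("threshold", "sign", params = list(feature = feature_name))
  majority <- names(which.max(table(y)))
  if (length(unique(x)) < 2) {
    warning("constant feature: threshold model degenerates to the null sign model")
    backend <- list(kind = "threshold", feature = feature_name, threshold = -Inf,
                    label_ge = majority, label_lt = majority, accuracy = mean(y == majority))
  } else {
    v <- sort(unique(x))
    cand <- c(-Inf, (v[-1] + v[-length(v)]) / 2, Inf)
    best <- list(acc = -1)
    for (t in cand) {
      hit <- x >= t
      for (dir in c("ge_negative", "ge_positive")) {
        lab_ge <- if (dir == "ge_negative") "negative" else "positive"
        lab_lt <- setdiff(SIGN_LEVELS, lab_ge)
        acc <- mean(ifelse(hit, lab_ge, lab_lt) == y)
        if (acc > best$acc)
          best <- list(acc = acc, t = t, lab_ge = lab_ge, lab_lt = lab_lt)
      }
    }
    backend <- list(kind = "threshold", feature = feature_name, threshold = best$t,
                    label_ge = best$lab_ge, label_lt = best$lab_lt, accuracy = best$acc)
  }
  structure(list(spec = spec, backend = backend, schema = colnames(X),
                 standardize = NULL,
                 search = list(n_configs = NA_integer_, cv_score = NA_real_,
                               hyperparameters = list(threshold = backend$threshold)),
                 train_summary = list(majority_sign = majority),
                 n_train = length(y)),
            class = "interaction_model")
}
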