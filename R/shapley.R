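# Model-agnostic Shapley attributions with a marginal-expectation value
# function: v(S) = mean over background rows b of f(x_S, b_rest). Exact
# enumeration for small feature counts, seeded permutation sampling otherwise.
# Both modes satisfy local accuracy exactly (the permutation walk telescopes),
# so base value + row attributions always reproduce the model output.

# Numeric model output used for attribution: predicted strength, or the
# positive-class score for sign models.
model_fun <- function(model) {
  if (is.function(model)) return(model)
  stopifnot(inherits(model, "interaction_model"))
  if (model$spec$task == "sign") {
    function(X) predict(model, X, type = "score")
  } else if (model$spec$task == "strength") {
    function(X) predict(model, X)
  } else stop("attribution supports sign and strength models")
}

#' Shapley feature attributions for model predictions
#'
#' Decomposes each row's prediction into per-feature contributions summing
#' (with the base value, the mean prediction over the background sample) to
#' the model output. `method = "exact_small"` enumerates all feature
#' coalitions (<= 12 features); `"sampling"` averages seeded random feature
#' permutations and is model-size agnostic.
#'
#' @param model An `interaction_model` (strength, or sign with scores), or a
#'   function mapping a feature matrix to numeric outputs.
#' @param features Rows to attribute (feature table or matrix).
#' @param background Background feature rows defining the marginal
#'   expectation; defaults to a seeded sample of up to `background_size` rows
#'   of `features`. Pass the training table for training-marginal baselines.
#' @param method `"auto"` (exact when p <= 12 would be cheap, else sampling),
#'   `"exact_small"` or `"sampling"`.
#' @param n_permutations Permutations per row for sampling (default 30).
#' @param background_size Background sample cap (default 100).
#' @param seed Seed for background sampling and permutations.
#' @param tol Local-accuracy tolerance; violation is an error with
#'   diagnostics (default 1e-6).
#' @return An `attribution_table`: matrix `phi` (rows x features), `base`,
#'   `prediction`, `feature_values`, and `importance` (mean absolute
#'   attribution per feature, the ranking key).
#' @export
attribute_predictions <- function(model, features, background = NULL,
                                  method = c("auto", "exact_small", "sampling"),
                                  n_permutations = 30, background_size = 100,
                                  seed = 1, tol = 1e-6) {
  method <- match.arg(method)
  f <- model_fun(model)
  schema <- if (inherits(model, "interaction_model")) model$schema else NULL
  X <- feature_matrix(features, schema = schema)
  p <- ncol(X)
  if (method == "auto") method <- if (p <= 8) "exact_small" else "sampling"
  if (method == "exact_small" && p > 12)
    stop("exact enumeration limited to 12 features; use method = 'sampling'")
  Bg <- if (is.null(background)) X else feature_matrix(background, schema = schema)
  with_seed(stage_seed(seed, 40), {
    if (nrow(Bg) > background_size)
      Bg <- Bg[sample(nrow(Bg), background_size), , drop = FALSE]
    perms <- lapply(seq_len(n_permutations), function(i) sample.int(p))
  })
  nb <- nrow(Bg)
  base <- mean(f(Bg))
  fx <- f(X)
  phi <- matrix(0, nrow(X), p, dimnames = list(NULL, colnames(X)))

  if (method == "exact_small") {
    masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
    sizes <- rowSums(masks)
    # v(S) for every coalition, batched into one model call per row
    for (i in seq_len(nrow(X))) {
      big <- Bg[rep(seq_len(nb), nrow(masks)), , drop = FALSE]
      sel <- masks[rep(seq_len(nrow(masks)), each = nb), , drop = FALSE]
      xrep <- X[rep(i, nrow(big)), , drop = FALSE]
      big[sel] <- xrep[sel]
      v <- colMeans(matrix(f(big), nrow = nb))
      for (j in seq_len(p)) {
        without <- which(!masks[, j])
        with_j <- without + 2^(j - 1)     # expand.grid order: bit j toggles block
        s <- sizes[without]
        w <- factorial(s) * factorial(p - s - 1) / factorial(p)
        phi[i, j] <- sum(w * (v[with_j] - v[without]))
      }
    }
  } else {
    for (i in seq_len(nrow(X))) {
      acc <- numeric(p)
      for (pm in perms) {
        # walk the permutation; batch the p-1 intermediate coalitions
        if (p > 1) {
          sel <- matrix(FALSE, p - 1, p)
          for (k in seq_len(p - 1)) sel[k, pm[seq_len(k)]] <- TRUE
          big <- Bg[rep(seq_len(nb), p - 1), , drop = FALSE]
          selrep <- sel[rep(seq_len(p - 1), each = nb), , drop = FALSE]
          xrep <- X[rep(i, nrow(big)), , drop = FALSE]
          big[selrep] <- xrep[selrep]
          v_mid <- colMeans(matrix(f(big), nrow = nb))
        } else v_mid <- numeric(0)
        v_seq <- c(base, v_mid, fx[i])
        acc[pm] <- acc[pm] + diff(v_seq)
      }
      phi[i, ] <- acc / length(perms)
    }
  }
  resid <- abs(base + rowSums(phi) - fx)
  if (any(resid > tol))
    stop(sprintf("local accuracy violated: max residual %.3g over tolerance %.3g",
                 max(resid), tol))
  structure(list(phi = phi, base = base, prediction = fx,
                 feature_values = X,
                 importance = sort(colMeans(abs(phi)), decreasing = TRUE)),
            class = "attribution_table")
}

#' @export
print.attribution_table <- function(x, ...) {
  cat(sprintf("attribution_table: %d rows x %d features (base value %.4f)\n",
              nrow(x$phi), ncol(x$phi), x$base))
  cat("feature importance (mean |attribution|):\n")
  print(round(x$importance, 4))
  invisible(x)
}

#' Beeswarm-style attribution plot
#'
#' One jittered horizontal band per feature (importance-ranked), points at
#' their attribution values, colored by the within-feature rank of the
#' feature value (light = low, dark = high).
#'
#' @param x An `attribution_table`.
#' @param top Number of features to show (default 10).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.attribution_table <- function(x, top = 10, ...) {
  feats <- names(x$importance)[seq_len(min(top, length(x$importance)))]
  k <- length(feats)
  pal <- grDevices::colorRampPalette(c("#ffd92f", "#4575b4"))(100)
  graphics::plot(NA, xlim = range(x$phi[, feats]), ylim = c(0.5, k + 0.5),
                 yaxt = "n", xlab = "attribution (model output units)",
                 ylab = "", ...)
  graphics::axis(2, at = k:1, labels = feats, las = 2, cex.axis = 0.7)
  for (i in seq_len(k)) {
    v <- x$phi[, feats[i]]
    val <- x$feature_values[, feats[i]]
    colidx <- pmax(1, ceiling(rank(val) / length(val) * 100))
    graphics::points(v, jitter(rep(k - i + 1, length(v)), amount = 0.25),
                     col = pal[colidx], pch = 16, cex = 0.5)
  }
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Write an attribution table to CSV
#'
#' @param at An `attribution_table`.
#' @param path Output CSV (one row per attributed prediction; per-feature
#'   attribution columns prefixed `phi_`).
#' @export
write_attributions <- function(at, path) {
  df <- data.frame(prediction = at$prediction, base = at$base,
                   at$phi, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("phi_", colnames(at$phi))
  write_csv_precise(df, path)
}
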