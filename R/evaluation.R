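# Evaluation: train/test splits, classification and regression metrics,
# and the error-structure profile.

#' Split effect records into train and test sets
#'
#' Uniform random split; for sign-type work the split is stratified by sign
#' by default, which stabilizes MCC on imbalanced data (set
#' `stratify = FALSE` for a plain random split). An optional pair-grouped
#' split keeps both directions of a species pair on the same side.
#'
#' @param records Data.frame of effect records or a `feature_table`.
#' @param test_frac Test fraction in (0, 1) (default 0.2).
#' @param seed Integer seed.
#' @param stratify Stratify by the `sign` column when present (default TRUE).
#' @param group_pairs Keep each unordered species pair (across directions and
#'   carbons) entirely in one split (default FALSE, matching a record-level
#'   random split).
#' @return List with `train` and `test` data.frames (disjoint, exhaustive).
#' @export
split_train_test <- function(records, test_frac = 0.2, seed = 1,
                             stratify = TRUE, group_pairs = FALSE) {
  stopifnot(test_frac > 0, test_frac < 1)
  n <- nrow(records)
  with_seed(stage_seed(seed, 5), {
    if (group_pairs) {
      pair <- paste(pmin(records$affected, records$affecting),
                    pmax(records$affected, records$affecting), sep = "\r")
      up <- unique(pair)
      te_pairs <- sample(up, max(1, round(test_frac * length(up))))
      te <- pair %in% te_pairs
    } else if (stratify && "sign" %in% names(records)) {
      te <- logical(n)
      for (s in unique(records$sign)) {
        idx <- which(records$sign == s)
        te[sample(idx, round(test_frac * length(idx)))] <- TRUE
      }
    } else {
      te <- logical(n)
      te[sample(n, round(test_frac * n))] <- TRUE
    }
  })
  if (!any(te) || all(te)) stop("split produced an empty train or test set")
  out <- list(train = records[!te, , drop = FALSE], test = records[te, , drop = FALSE])
  for (nm in names(out)) {
    rownames(out[[nm]]) <- NULL
    attributes(out[[nm]])[c("feature_cols", "carbon_projection")] <-
      attributes(records)[c("feature_cols", "carbon_projection")]
    class(out[[nm]]) <- class(records)
  }
  out
}

# Matthews correlation coefficient from label vectors; 0 (with warning from
# classification_metrics) when a marginal is degenerate.
mcc <- function(y_true, y_pred, positive = "positive") {
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Classification metrics for effect-sign predictions
#'
#' Standard confusion-matrix metrics plus MCC
#' (`(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, 0 with a warning
#' when a denominator term vanishes) and, when scores are supplied, ROC-AUC.
#'
#' @param y_true,y_pred Label vectors (`"positive"`/`"negative"`).
#' @param scores Optional positive-class scores for ROC-AUC.
#' @param positive Positive-class label.
#' @return A `metrics_report` list: n, TP/FP/TN/FN, accuracy, mcc, precision
#'   (PPV), recall (TPR), tnr, npv, and auc when scores are given.
#' @export
classification_metrics <- function(y_true, y_pred, scores = NULL, positive = "positive") {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  if (den == 0) warning("degenerate confusion matrix: MCC set to 0")
  rate <- function(a, b) if (a + b == 0) NA_real_ else a / (a + b)
  rep <- list(task = "sign", n = length(y_true), tp = tp, fp = fp, tn = tn, fn = fn,
              accuracy = (tp + tn) / length(y_true),
              mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den,
              precision = rate(tp, fp), recall = rate(tp, fn),
              tpr = rate(tp, fn), tnr = rate(tn, fp),
              ppv = rate(tp, fp), npv = rate(tn, fn))
  if (!is.null(scores)) {
    neg <- setdiff(unique(y_true), positive)[1]
    r <- pROC::roc(response = y_true, predictor = scores, quiet = TRUE,
                   direction = "<", levels = c(neg, positive))
    rep$auc <- as.numeric(pROC::auc(r))
  }
  structure(rep, class = "metrics_report")
}

#' Regression metrics for effect-strength predictions
#'
#' RMSE, coefficient of determination, and NRMSE — the RMSE divided by the
#' population standard deviation (ddof = 0) of the observed effects, so a
#' train-mean predictor scores exactly 1 on its own training set.
#'
#' @param y_true,y_pred Numeric vectors (length >= 2).
#' @return A `metrics_report` list: n, rmse, nrmse, r2.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("need at least two observations")
  sdp <- sqrt(mean((y_true - mean(y_true))^2))
  if (sdp == 0) stop("degenerate test targets: zero standard deviation")
  rmse <- sqrt(mean((y_true - y_pred)^2))
  structure(list(task = "strength", n = length(y_true), rmse = rmse,
                 nrmse = rmse / sdp,
                 r2 = 1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  if (x$task == "sign") {
    cat(sprintf("sign metrics (n=%d): accuracy %.3f  MCC %.3f  precision %.3f  recall %.3f\n",
                x$n, x$accuracy, x$mcc, x$precision, x$recall))
    cat(sprintf("  TP=%d FP=%d TN=%d FN=%d  TNR %.3f  NPV %.3f%s\n",
                x$tp, x$fp, x$tn, x$fn, x$tnr, x$npv,
                if (!is.null(x$auc)) sprintf("  AUC %.3f", x$auc) else ""))
  } else {
    cat(sprintf("strength metrics (n=%d): RMSE %.3f  NRMSE %.3f  R2 %.3f\n",
                x$n, x$rmse, x$nrmse, x$r2))
  }
  invisible(x)
}

#' Sign-error counts as a function of true effect strength
#'
#' Bins the true effect strengths and counts false positives and false
#' negatives per bin (intervals are left-closed, `[a, b)`), profiling where on
#' the strength axis a sign classifier errs.
#'
#' @param y_true_strength Numeric true effects.
#' @param y_true_sign,y_pred_sign Label vectors.
#' @param bins Either a vector of breaks or a single bin width (breaks are
#'   then built to span the data, aligned on multiples of the width).
#' @return Data.frame with `bin_lo`, `bin_hi`, `fp`, `fn`; column sums equal
#'   the overall FP/FN counts.
#' @export
error_vs_strength_profile <- function(y_true_strength, y_true_sign, y_pred_sign,
                                      bins = 0.1) {
  stopifnot(length(y_true_strength) == length(y_true_sign),
            length(y_true_sign) == length(y_pred_sign))
  if (length(bins) == 1) {
    lo <- floor(min(y_true_strength) / bins) * bins
    hi <- ceiling(max(y_true_strength) / bins) * bins
    if (hi <= lo) hi <- lo + bins
    breaks <- seq(lo, hi + bins, by = bins)
  } else breaks <- bins
  idx <- cut(y_true_strength, breaks = breaks, right = FALSE, include.lowest = FALSE)
  fp <- y_true_sign == "negative" & y_pred_sign == "positive"
  fn <- y_true_sign == "positive" & y_pred_sign == "negative"
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             fp = as.vector(tapply(fp, idx, sum, default = 0)),
             fn = as.vector(tapply(fn, idx, sum, default = 0)))
}
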