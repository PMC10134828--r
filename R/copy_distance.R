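# How copy-model accuracy relates to phylogenetic distance: for every ordered
# (target, source) species pair, predict all of the target's effects by
# substituting the source species in the same role, same partner, same
# carbon, and score the copies against the measured effects.

#' Copy-model accuracy versus phylogenetic distance
#'
#' @param dataset An `interaction_dataset` (>= 3 species).
#' @param metric `"nrmse"` (error; default), `"mcc"` or `"accuracy"` on
#'   signs.
#' @return List of class `copy_distance`: `table` (one row per (target,
#'   source) pair: metric value, phylogenetic distance, `same_clade` flag
#'   from a two-group cut of the distance matrix, `n`), and `pearson_r`, the
#'   correlation between metric value and distance across pairs.
#' @export
copy_accuracy_vs_distance <- function(dataset, metric = c("nrmse", "mcc", "accuracy")) {
  metric <- match.arg(metric)
  d <- dataset$phylo_dist
  sp <- rownames(d)
  if (length(sp) < 3) stop("need at least 3 species")
  clade <- stats::cutree(stats::hclust(stats::as.dist(d), method = "average"), k = 2)
  eff <- dataset$effects
  key <- paste(eff$affected, eff$affecting, eff$carbon, sep = "\r")
  idx <- stats::setNames(seq_along(key), key)
  rows <- list()
  for (target in sp) {
    trec <- eff[eff$affected == target | eff$affecting == target, , drop = FALSE]
    for (source in setdiff(sp, target)) {
      sub_a <- ifelse(trec$affected == target, source, trec$affected)
      sub_b <- ifelse(trec$affecting == target, source, trec$affecting)
      ok <- sub_a != sub_b
      j <- idx[paste(sub_a, sub_b, trec$carbon, sep = "\r")]
      ok <- ok & !is.na(j)
      if (sum(ok) < 2) {
        warning("source ", source, " has too few matching records for target ",
                target, "; pair skipped")
        next
      }
      truth <- trec$effect[ok]
      copied <- eff$effect[j[ok]]
      val <- switch(metric,
        nrmse = if (stats::sd(truth) == 0) NA_real_
                else regression_metrics(truth, copied)$nrmse,
        mcc = mcc(trec$sign[ok], eff$sign[j[ok]]),
        accuracy = mean(trec$sign[ok] == eff$sign[j[ok]]))
      rows[[length(rows) + 1L]] <- data.frame(
        target = target, source = source, metric = metric, value = val,
        phylo_dist = d[target, source],
        same_clade = clade[target] == clade[source], n = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- is.finite(tab$value)
  structure(list(table = tab,
                 pearson_r = stats::cor(tab$value[ok], tab$phylo_dist[ok])),
            class = "copy_distance")
}

#' @export
print.copy_distance <- function(x, ...) {
  cat(sprintf("copy accuracy vs phylogenetic distance: %d (target, source) pairs\n",
              nrow(x$table)))
  cat(sprintf("  Pearson r(%s, distance) = %.3f\n", x$table$metric[1], x$pearson_r))
  invisible(x)
}
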