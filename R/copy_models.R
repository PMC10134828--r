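# Copy-model baselines: predict an interaction by copying the recorded
# interaction of the nearest species (phylogenetic copy) or the nearest
# carbon environment (metabolic copy).

effect_lookup <- function(effects) {
  key <- paste(effects$affected, effects$affecting, effects$carbon, sep = "\r")
  stats::setNames(seq_along(key), key)
}

#' Phylogenetic copy prediction for an uncultured species
#'
#' For each query interaction involving the uncultured species, finds the
#' phylogenetically closest species with available data (distance ties broken
#' lexicographically), and copies its recorded effect with the same partner in
#' the same carbon environment; if that record is missing, falls back to the
#' next-closest species. The uncultured species may appear in either role;
#' the copy source replaces it in that role.
#'
#' @param dataset An `interaction_dataset` (its effects are the copy source;
#'   records involving any excluded species are never used).
#' @param query Data.frame with columns `affected`, `affecting`, `carbon`.
#' @param excluded_species Character vector of species treated as uncultured;
#'   the first element is the query species being predicted.
#' @param task `"strength"` (copied effect value) or `"sign"`.
#' @return Vector of predictions (numeric or character) with attribute
#'   `source` naming the copied species per query row.
#' @export
phylo_copy_predict <- function(dataset, query, excluded_species,
                               task = c("strength", "sign")) {
  task <- match.arg(task)
  target <- excluded_species[1]
  d <- dataset$phylo_dist
  cand <- setdiff(rownames(d), excluded_species)
  cand <- cand[order(d[target, cand], cand)]
  eff <- dataset$effects
  eff <- eff[!(eff$affected %in% excluded_species | eff$affecting %in% excluded_species), ]
  idx <- effect_lookup(eff)
  out <- if (task == "strength") numeric(nrow(query)) else character(nrow(query))
  src <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    qa <- query$affected[i]; qb <- query$affecting[i]; qc <- query$carbon[i]
    found <- FALSE
    for (s in cand) {
      k <- if (qa == target) paste(s, qb, qc, sep = "\r")
           else if (qb == target) paste(qa, s, qc, sep = "\r")
           else stop("query row does not involve the uncultured species")
      j <- idx[k]
      if (!is.na(j)) {
        out[i] <- if (task == "strength") eff$effect[j] else eff$sign[j]
        src[i] <- s
        found <- TRUE
        break
      }
    }
    if (!found) stop("no copyable interaction for query (",
                     qa, ", ", qb, ", ", qc, ")")
  }
  attr(out, "source") <- src
  out
}

#' Metabolic copy prediction for an unobserved carbon environment
#'
#' Mirror of [phylo_copy_predict()] with environments ranked by the Euclidean
#' distance between their metabolic profiles (the vector of all species'
#' monoculture yields in the environment; the held-out environment's own
#' monoculture profile is allowed — its pair data are not). Copies the same
#' ordered pair's effect in the most similar environment, falling back to the
#' next most similar when the record is missing.
#'
#' @param dataset An `interaction_dataset`.
#' @param query Data.frame with columns `affected`, `affecting`, `carbon`
#'   (all in the excluded environment).
#' @param excluded_carbon Carbon id(s) treated as unobserved; the first is the
#'   query environment.
#' @param task `"strength"` or `"sign"`.
#' @return Predictions with attribute `source` (copied carbon per row).
#' @export
metabolic_copy_predict <- function(dataset, query, excluded_carbon,
                                   task = c("strength", "sign")) {
  task <- match.arg(task)
  target <- excluded_carbon[1]
  prof <- impute_mono(dataset$mono_yields)   # species x carbons
  dmat <- as.matrix(stats::dist(t(prof)))
  cand <- setdiff(colnames(prof), excluded_carbon)
  cand <- cand[order(dmat[target, cand], cand)]
  eff <- dataset$effects
  eff <- eff[!(eff$carbon %in% excluded_carbon), ]
  idx <- effect_lookup(eff)
  out <- if (task == "strength") numeric(nrow(query)) else character(nrow(query))
  src <- character(nrow(query))
  for (i in seq_len(nrow(query))) {
    qa <- query$affected[i]; qb <- query$affecting[i]
    found <- FALSE
    for (cb in cand) {
      j <- idx[paste(qa, qb, cb, sep = "\r")]
      if (!is.na(j)) {
        out[i] <- if (task == "strength") eff$effect[j] else eff$sign[j]
        src[i] <- cb
        found <- TRUE
        break
      }
    }
    if (!found) stop("no copyable interaction for query (",
                     qa, ", ", qb, ", ", target, ")")
  }
  attr(out, "source") <- src
  out
}
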