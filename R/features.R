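# Feature construction: phylogenetic PCs, carbon metabolic-profile PCs (with
# out-of-sample projection for held-out environments), metabolic distance and
# monoculture yields, joined per directed effect record.

# Deterministic eigenvector sign: flip each component so its largest-magnitude
# loading is positive.
pin_signs <- function(rotation, scores) {
  for (j in seq_len(ncol(rotation))) {
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(rotation = rotation, scores = scores)
}

#' Phylogenetic principal components
#'
#' Treats each species' row of the phylogenetic distance matrix as its feature
#' vector, column-centers, and extracts the top principal components (plain
#' PCA on the rows, not classical MDS). The first two components typically
#' capture the clade structure (>95% of variance for clade-structured trees).
#'
#' @param phylo_dist Symmetric zero-diagonal distance matrix.
#' @param n_components Number of components (default 2).
#' @return List with `scores` (species x components, deterministic sign),
#'   `rotation`, `center`, `explained_var` (ratios for the returned
#'   components).
#' @export
phylo_pcs <- function(phylo_dist, n_components = 2) {
  check_dist_matrix(phylo_dist)
  p <- stats::prcomp(phylo_dist, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(p$rotation))
  tot <- sum(p$sdev^2)
  sc <- p$x[, seq_len(k), drop = FALSE]
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  if (tot > 0) {
    ps <- pin_signs(rot, sc); rot <- ps$rotation; sc <- ps$scores
  }
  colnames(sc) <- colnames(rot) <- paste0("PC", seq_len(k))
  list(scores = sc, rotation = rot, center = p$center,
       explained_var = if (tot > 0) p$sdev[seq_len(k)]^2 / tot else rep(0, k))
}

# Impute missing monoculture yields by the species' mean across carbons
# (profile-based features only; per-row mono features are never imputed).
impute_mono <- function(mono_yields) {
  m <- mono_yields
  for (i in seq_len(nrow(m))) {
    miss <- is.na(m[i, ])
    if (any(miss)) m[i, miss] <- mean(m[i, !miss])
  }
  m
}

#' Carbon metabolic-profile principal components
#'
#' Each carbon environment is represented by its metabolic profile — the
#' vector of all species' monoculture yields in that carbon. PCA is performed
#' over carbons (column-centered profiles); the fitted center and loadings are
#' returned so held-out environments can be projected without refitting.
#'
#' @param mono_yields Species x carbon yield matrix (missing entries imputed
#'   by the species' mean across carbons).
#' @param n_components Number of components (default 4).
#' @return An object of class `carbon_projection`: `scores` (carbon x
#'   components), `rotation`, `center`, `explained_var`, `species` (profile
#'   ordering).
#' @export
carbon_pcs <- function(mono_yields, n_components = 4) {
  if (ncol(mono_yields) < n_components + 1)
    stop("need at least n_components + 1 carbons")
  M <- t(impute_mono(mono_yields))      # carbons x species
  Mc <- scale(M, center = TRUE, scale = FALSE)
  rk <- qr(Mc)$rank
  if (n_components > rk)
    stop(sprintf("requested %d components but centered profile matrix has rank %d",
                 n_components, rk))
  p <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  sc <- p$x[, seq_len(n_components), drop = FALSE]
  rot <- p$rotation[, seq_len(n_components), drop = FALSE]
  ps <- pin_signs(rot, sc)
  colnames(ps$scores) <- colnames(ps$rotation) <- paste0("PC", seq_len(n_components))
  structure(list(scores = ps$scores, rotation = ps$rotation, center = p$center,
                 explained_var = p$sdev[seq_len(n_components)]^2 / sum(p$sdev^2),
                 species = colnames(M)),
            class = "carbon_projection")
}

#' Project a held-out carbon profile onto fitted carbon PCs
#'
#' Coordinates are `t(loadings) %*% (profile - center)`; the PCA is never
#' refit, matching the treatment of environments absent from training.
#'
#' @param projection A `carbon_projection` fitted without the held-out carbon.
#' @param heldout_profile Named numeric vector of species monoculture yields
#'   (same species ordering as the fit; NAs imputed by the profile mean).
#' @return Numeric vector of PC coordinates.
#' @export
project_heldout_carbon <- function(projection, heldout_profile) {
  stopifnot(inherits(projection, "carbon_projection"))
  if (length(heldout_profile) != length(projection$species))
    stop("profile species dimension mismatch")
  if (!is.null(names(heldout_profile))) {
    if (!setequal(names(heldout_profile), projection$species))
      stop("profile species do not match the fitted projection")
    heldout_profile <- heldout_profile[projection$species]
  }
  if (any(is.na(heldout_profile)))
    heldout_profile[is.na(heldout_profile)] <- mean(heldout_profile, na.rm = TRUE)
  drop(crossprod(projection$rotation, heldout_profile - projection$center))
}

#' Metabolic distance between two species
#'
#' Euclidean distance between the species' monoculture yield profiles across
#' all carbons (missing entries imputed by the species' mean yield).
#'
#' @param mono_yields Species x carbon yield matrix.
#' @param species_a,species_b Species ids.
#' @return Non-negative scalar.
#' @export
metabolic_distance <- function(mono_yields, species_a, species_b) {
  if (!all(c(species_a, species_b) %in% rownames(mono_yields)))
    stop("unknown species")
  m <- impute_mono(mono_yields)
  sqrt(sum((m[species_a, ] - m[species_b, ])^2))
}

# All pairwise metabolic distances at once.
metabolic_distance_matrix <- function(mono_yields) {
  as.matrix(stats::dist(impute_mono(mono_yields)))
}

#' Options controlling feature-table assembly
#'
#' @param drop_monoculture_features Drop `mono_affected`, `mono_affecting` and
#'   `metab_dist` (the "no monoculture information" ablation tier).
#' @param drop_phylo,drop_carbon Drop the phylogenetic / carbon PC blocks.
#' @param carbon_onehot Add a one-hot carbon indicator block.
#' @param chemistry Optional data.frame of carbon chemistry descriptors
#'   (first column `carbon`), joined by carbon id.
#' @param pathways Optional binary species x pathway matrix (row names =
#'   species); affected and affecting species' rows are appended.
#' @param reciprocal_effect Add the measured opposite-direction effect as a
#'   feature.
#' @param log_mono Use log-scaled monoculture yields for the per-row mono
#'   features (default raw).
#' @param n_phylo_pcs,n_carbon_pcs Component counts (defaults 2 and 4).
#' @param exclude_carbon_from_pca Optional carbon id: the carbon PCA is fitted
#'   without this environment and its coordinates obtained by projection
#'   (held-out environment treatment).
#' @return A `feature_options` list.
#' @export
feature_options <- function(drop_monoculture_features = FALSE, drop_phylo = FALSE,
                            drop_carbon = FALSE, carbon_onehot = FALSE,
                            chemistry = NULL, pathways = NULL,
                            reciprocal_effect = FALSE, log_mono = FALSE,
                            n_phylo_pcs = 2, n_carbon_pcs = 4,
                            exclude_carbon_from_pca = NULL) {
  structure(list(drop_monoculture_features = drop_monoculture_features,
                 drop_phylo = drop_phylo, drop_carbon = drop_carbon,
                 carbon_onehot = carbon_onehot, chemistry = chemistry,
                 pathways = pathways, reciprocal_effect = reciprocal_effect,
                 log_mono = log_mono, n_phylo_pcs = n_phylo_pcs,
                 n_carbon_pcs = n_carbon_pcs,
                 exclude_carbon_from_pca = exclude_carbon_from_pca),
            class = "feature_options")
}

#' Assemble the model feature table
#'
#' One row per directed effect record, keyed by (affected, affecting, carbon),
#' carrying the labels (`effect`, `sign`) and the feature columns. Mandatory
#' features: monoculture yields of both species in the focal carbon, metabolic
#' distance, two phylogenetic PCs per species, four carbon PCs (11 columns).
#' Rows whose per-row monoculture features are unavailable are excluded (never
#' imputed), mirroring the screen's dropped combinations.
#'
#' @param dataset An `interaction_dataset`.
#' @param options A [feature_options()] list.
#' @return A `feature_table` data.frame; attribute `feature_cols` names the
#'   feature columns (stable order) and `carbon_projection` holds the fitted
#'   carbon PCA.
#' @export
assemble_features <- function(dataset, options = feature_options()) {
  stopifnot(inherits(dataset, "interaction_dataset"))
  eff <- dataset$effects
  my <- dataset$mono_yields
  ft <- eff[, c("affected", "affecting", "carbon", "effect", "sign")]
  cols <- character(0)

  if (!options$drop_monoculture_features) {
    ma <- my[cbind(match(ft$affected, rownames(my)), match(ft$carbon, colnames(my)))]
    mb <- my[cbind(match(ft$affecting, rownames(my)), match(ft$carbon, colnames(my)))]
    if (options$log_mono) { ma <- log(ma); mb <- log(mb) }
    md <- metabolic_distance_matrix(my)
    ft$mono_affected <- ma
    ft$mono_affecting <- mb
    ft$metab_dist <- md[cbind(ft$affected, ft$affecting)]
    cols <- c(cols, "mono_affected", "mono_affecting", "metab_dist")
  }
  if (!options$drop_phylo) {
    pp <- phylo_pcs(dataset$phylo_dist, options$n_phylo_pcs)$scores
    for (j in seq_len(ncol(pp))) {
      ft[[paste0("phylo_pc", j, "_affected")]] <- pp[ft$affected, j]
      ft[[paste0("phylo_pc", j, "_affecting")]] <- pp[ft$affecting, j]
    }
    cols <- c(cols, as.vector(t(outer(paste0("phylo_pc", seq_len(ncol(pp))),
                                      c("_affected", "_affecting"), paste0))))
  }
  proj <- NULL
  if (!options$drop_carbon) {
    if (!is.null(options$exclude_carbon_from_pca)) {
      hold <- options$exclude_carbon_from_pca
      proj <- carbon_pcs(my[, setdiff(colnames(my), hold), drop = FALSE],
                         options$n_carbon_pcs)
      prof <- impute_mono(my)[projection_species(proj), hold]
      held_coords <- project_heldout_carbon(proj, prof)
      cc <- rbind(proj$scores, matrix(held_coords, 1,
                                      dimnames = list(hold, colnames(proj$scores))))
    } else {
      proj <- carbon_pcs(my, options$n_carbon_pcs)
      cc <- proj$scores
    }
    for (j in seq_len(options$n_carbon_pcs))
      ft[[paste0("carbon_pc", j)]] <- cc[ft$carbon, j]
    cols <- c(cols, paste0("carbon_pc", seq_len(options$n_carbon_pcs)))
  }
  if (options$carbon_onehot) {
    for (cb in sort(unique(ft$carbon))) {
      nm <- paste0("carbon_is_", cb)
      ft[[nm]] <- as.numeric(ft$carbon == cb)
      cols <- c(cols, nm)
    }
  }
  if (!is.null(options$chemistry)) {
    ch <- options$chemistry
    if (!is.data.frame(ch) || names(ch)[1] != "carbon")
      stop("chemistry table must be a data.frame with first column 'carbon'")
    idx <- match(ft$carbon, ch$carbon)
    if (any(is.na(idx))) stop("chemistry table missing some carbons")
    for (nm in names(ch)[-1]) {
      ft[[paste0("chem_", nm)]] <- ch[[nm]][idx]
      cols <- c(cols, paste0("chem_", nm))
    }
  }
  if (!is.null(options$pathways)) {
    pw <- options$pathways
    if (is.null(rownames(pw))) stop("pathway matrix needs species row names")
    if (!all(unique(c(ft$affected, ft$affecting)) %in% rownames(pw)))
      stop("pathway matrix missing some species")
    for (j in seq_len(ncol(pw))) {
      nmj <- colnames(pw)[j] %||% paste0("pw", j)
      ft[[paste0("path_", nmj, "_affected")]] <- pw[ft$affected, j]
      ft[[paste0("path_", nmj, "_affecting")]] <- pw[ft$affecting, j]
      cols <- c(cols, paste0("path_", nmj, c("_affected", "_affecting")))
    }
  }
  if (options$reciprocal_effect) {
    key <- paste(eff$affected, eff$affecting, eff$carbon, sep = "\r")
    mirror <- paste(ft$affecting, ft$affected, ft$carbon, sep = "\r")
    ft$reciprocal_effect <- eff$effect[match(mirror, key)]
    cols <- c(cols, "reciprocal_effect")
  }
  keep <- stats::complete.cases(ft[, cols, drop = FALSE])
  if (any(!keep))
    message(sprintf("feature table: %d rows excluded for missing feature values", sum(!keep)))
  ft <- ft[keep, , drop = FALSE]
  rownames(ft) <- NULL
  attr(ft, "feature_cols") <- cols
  attr(ft, "carbon_projection") <- proj
  class(ft) <- c("feature_table", "data.frame")
  ft
}

projection_species <- function(proj) proj$species

#' Feature column names of a feature table
#' @param ft A `feature_table`.
#' @return Character vector (stable, documented order).
#' @export
feature_columns <- function(ft) attr(ft, "feature_cols")

#' Write / read a feature table CSV
#'
#' @param ft A `feature_table`.
#' @param path CSV path. Key and label columns come first, then the feature
#'   columns in their assembly order; the header preserves that order.
#' @return `path` (write); a `feature_table` (read, feature columns = all
#'   columns after `sign`).
#' @export
write_features <- function(ft, path) {
  write_csv_precise(as.data.frame(ft), path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- c("affected", "affecting", "carbon", "effect", "sign")
  attr(df, "feature_cols") <- setdiff(names(df), base)
  class(df) <- c("feature_table", "data.frame")
  df
}
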