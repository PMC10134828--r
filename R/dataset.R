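# Dataset construction: replicate-level growth tables -> directed effects.
#
# The central quantity is the one-way growth effect of species B on species A
# in carbon environment c:
#
#   effect(A <- B, c) = log( mean coculture yield of A with B in c /
#                            mean monoculture yield of A in c )
#
# Natural log; replicate yields are averaged before taking the ratio because
# mono and co droplets are unpaired. Negative effects mean inhibition,
# positive ones facilitation.

#' Validate a long-format growth table
#'
#' A growth table holds replicate-level endpoint yields, one row per droplet:
#' `species` (the measured species), `partner` (the cocultured species, or the
#' literal token `"MONO"` for monocultures), `carbon` (environment id),
#' `replicate` (positive integer) and `yield` (non-negative, in the screen's
#' fluorescence/OD units).
#'
#' @param x A data.frame with columns `species`, `partner`, `carbon`,
#'   `replicate`, `yield`.
#' @return The validated data.frame (invisibly classed `growth_table`).
#' @export
as_growth_table <- function(x) {
  need <- c("species", "partner", "carbon", "replicate", "yield")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("growth table needs columns: ", paste(need, collapse = ", "))
  if (nrow(x) == 0) stop("empty growth table")
  x <- x[, need]
  x$species <- as.character(x$species)
  x$partner <- as.character(x$partner)
  x$carbon <- as.character(x$carbon)
  x$replicate <- as.integer(x$replicate)
  x$yield <- as.numeric(x$yield)
  if (any(is.na(x$yield)) || any(x$yield < 0)) stop("yields must be non-negative and finite")
  if (any(x$replicate < 1)) stop("replicate indices must be positive")
  if (any(x$species == MONO)) stop("species id may not equal the MONO sentinel")
  key <- paste(x$species, x$partner, x$carbon, x$replicate, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (species, partner, carbon, replicate) keys")
  class(x) <- c("growth_table", "data.frame")
  x
}

#' Read a growth table from CSV
#'
#' @param path Path to a headered CSV with columns
#'   `species,partner,carbon,replicate,yield`; monoculture rows carry the
#'   partner token `"MONO"`.
#' @return A `growth_table` data.frame.
#' @export
read_growth_table <- function(path) {
  as_growth_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Drop culture groups observed with too few replicates
#'
#' Removes every (species, partner, carbon) group represented by fewer than
#' `min_reps` replicate droplets; the screen this mirrors dropped groups with
#' fewer than three replicates (about 7% of combinations).
#'
#' @param raw A `growth_table` (or coercible data.frame).
#' @param min_reps Minimum replicate count a group must reach (default 3).
#' @return The filtered `growth_table`; the dropped fraction is reported via
#'   `message()`.
#' @export
filter_min_replicates <- function(raw, min_reps = 3) {
  raw <- as_growth_table(raw)
  stopifnot(min_reps >= 1)
  key <- paste(raw$species, raw$partner, raw$carbon, sep = "\r")
  n_by <- table(key)
  keep <- n_by[key] >= min_reps
  dropped_groups <- sum(n_by < min_reps)
  message(sprintf("replicate filter: dropped %d of %d groups (%.1f%% of records)",
                  dropped_groups, length(n_by), 100 * mean(!keep)))
  out <- raw[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("no groups survive the replicate filter")
  rownames(out) <- NULL
  class(out) <- c("growth_table", "data.frame")
  out
}

# Mean monoculture yield matrix (species x carbon), NA where unobserved.
mono_yield_matrix <- function(filtered) {
  mono <- filtered[filtered$partner == MONO, , drop = FALSE]
  if (nrow(mono) == 0) stop("growth table contains no monoculture records")
  sp <- sort(unique(filtered$species))
  cb <- sort(unique(filtered$carbon))
  m <- matrix(NA_real_, length(sp), length(cb), dimnames = list(sp, cb))
  agg <- stats::aggregate(yield ~ species + carbon, data = mono, FUN = mean)
  m[cbind(match(agg$species, sp), match(agg$carbon, cb))] <- agg$yield
  m
}

#' Compute directed growth effects from a filtered growth table
#'
#' For every coculture group the effect on the measured species is the natural
#' log of the ratio between its mean coculture yield and its mean monoculture
#' yield in the same carbon. Records whose monoculture reference is missing, or
#' whose mono/co mean is zero, are dropped with a warning.
#'
#' @param filtered A replicate-filtered `growth_table`.
#' @return A data.frame of effect records with columns
#'   `affected, affecting, carbon, effect, sign` (`sign` is `"positive"` iff
#'   `effect > 0`, else `"negative"`).
#' @export
compute_effects <- function(filtered) {
  filtered <- as_growth_table(filtered)
  co <- filtered[filtered$partner != MONO, , drop = FALSE]
  if (nrow(co) == 0) stop("growth table contains no coculture records")
  mono <- mono_yield_matrix(filtered)
  agg <- stats::aggregate(yield ~ species + partner + carbon, data = co, FUN = mean)
  mono_mean <- mono[cbind(match(agg$species, rownames(mono)),
                          match(agg$carbon, colnames(mono)))]
  bad_mono <- is.na(mono_mean) | mono_mean == 0
  bad_co <- agg$yield == 0
  if (any(bad_mono))
    warning(sprintf("%d coculture groups dropped: missing or zero monoculture reference",
                    sum(bad_mono)))
  if (any(bad_co & !bad_mono))
    warning(sprintf("%d coculture groups dropped: zero coculture mean", sum(bad_co & !bad_mono)))
  keep <- !(bad_mono | bad_co)
  agg <- agg[keep, , drop = FALSE]
  eff <- log(agg$yield / mono_mean[keep])
  out <- data.frame(affected = agg$species, affecting = agg$partner,
                    carbon = agg$carbon, effect = eff,
                    sign = ifelse(eff > 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$affected, out$affecting, out$carbon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a two-way interaction from its two directed effects
#'
#' @param e_ab,e_ba Single-row effect records (the two directions of the same
#'   pair in the same carbon), or scalar signs/effects.
#' @return `"competition"` for (-,-), `"mutualism"` for (+,+), `"parasitism"`
#'   for mixed signs.
#' @export
label_pair_type <- function(e_ab, e_ba) {
  sgn <- function(e) {
    if (is.data.frame(e)) {
      stopifnot(nrow(e) == 1)
      e$sign
    } else if (is.character(e)) e else if (e > 0) "positive" else "negative"
  }
  if (is.data.frame(e_ab) && is.data.frame(e_ba)) {
    ok <- e_ab$affected == e_ba$affecting && e_ab$affecting == e_ba$affected &&
      e_ab$carbon == e_ba$carbon
    if (!ok) stop("effect records are not the two directions of one pair in one carbon")
  }
  s <- c(sgn(e_ab), sgn(e_ba))
  if (all(s == "negative")) "competition"
  else if (all(s == "positive")) "mutualism"
  else "parasitism"
}

#' Bundle effects, monoculture yields and phylogenetic distances
#'
#' @param effects Effect records as produced by [compute_effects()].
#' @param mono_yields Species x carbon matrix of mean monoculture yields
#'   (NA allowed for unobserved combinations).
#' @param phylo_dist Symmetric non-negative species x species distance matrix
#'   with zero diagonal, covering every species in `effects`.
#' @return An `interaction_dataset` list.
#' @export
interaction_dataset <- function(effects, mono_yields, phylo_dist) {
  stopifnot(is.data.frame(effects),
            all(c("affected", "affecting", "carbon", "effect", "sign") %in% names(effects)))
  if (any(effects$affected == effects$affecting)) stop("self-interactions are not allowed")
  if (any(!is.finite(effects$effect))) stop("effects must be finite")
  sp <- sort(unique(c(effects$affected, effects$affecting)))
  cb <- sort(unique(effects$carbon))
  if (!all(sp %in% rownames(mono_yields)))
    stop("mono_yields is missing species referenced by effects")
  if (!all(cb %in% colnames(mono_yields)))
    stop("mono_yields is missing carbons referenced by effects")
  check_dist_matrix(phylo_dist)
  if (!all(sp %in% rownames(phylo_dist)))
    stop("phylo_dist is missing species referenced by effects")
  structure(list(effects = effects, mono_yields = mono_yields, phylo_dist = phylo_dist),
            class = "interaction_dataset")
}

check_dist_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    stop("distance matrix needs matching row/column names")
  if (any(d < 0) || !isTRUE(all.equal(unname(d), unname(t(d)))) || any(diag(d) != 0))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal")
  invisible(d)
}

#' Build an interaction dataset from a raw growth table
#'
#' Convenience wrapper running the replicate filter, effect computation and
#' monoculture aggregation.
#'
#' @inheritParams filter_min_replicates
#' @param phylo_dist Distance matrix (or path; see [read_phylo_dist()]).
#' @param min_reps Replicate filter threshold.
#' @return An `interaction_dataset`.
#' @export
build_dataset <- function(raw, phylo_dist, min_reps = 3) {
  if (is.character(phylo_dist)) phylo_dist <- read_phylo_dist(phylo_dist)
  filtered <- filter_min_replicates(raw, min_reps)
  interaction_dataset(compute_effects(filtered), mono_yield_matrix(filtered), phylo_dist)
}

#' @export
print.interaction_dataset <- function(x, ...) {
  sp <- unique(c(x$effects$affected, x$effects$affecting))
  cat("interaction_dataset:", nrow(x$effects), "directed effects,",
      length(sp), "species,", length(unique(x$effects$carbon)), "carbons\n")
  cat(sprintf("  negative fraction: %.3f  effect range: [%.3f, %.3f]\n",
              mean(x$effects$sign == "negative"),
              min(x$effects$effect), max(x$effects$effect)))
  invisible(x)
}

#' Read a phylogenetic distance matrix
#'
#' Accepts either a square CSV with species ids as row/column labels, or a
#' newick tree from which patristic (cophenetic) distances are taken.
#'
#' @param path File path; files ending in `.nwk`, `.newick` or `.tree` (or
#'   whose first non-blank character is `(`) are parsed as newick.
#' @return Symmetric distance matrix with species names.
#' @export
read_phylo_dist <- function(path) {
  first <- substr(trimws(readLines(path, n = 1L, warn = FALSE)), 1, 1)
  if (grepl("\\.(nwk|newick|tree)$", path, ignore.case = TRUE) || identical(first, "(")) {
    tr <- ape::read.tree(path)
    d <- ape::cophenetic.phylo(tr)
    d <- d[order(rownames(d)), order(colnames(d))]
  } else {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    d <- as.matrix(df)
    colnames(d) <- colnames(df)
  }
  check_dist_matrix(d)
  d
}

#' Write / read the canonical effects CSV
#'
#' Numeric columns are written at full precision so a round trip reproduces
#' effects bit-exactly.
#'
#' @param effects Effect records.
#' @param path Output CSV path (`affected,affecting,carbon,effect,sign`).
#' @return `path` (write) or the effects data.frame (read).
#' @export
write_effects <- function(effects, path) {
  write_csv_precise(effects[, c("affected", "affecting", "carbon", "effect", "sign")], path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(affected = "character", affecting = "character",
                                 carbon = "character", effect = "numeric", sign = "character"))
}

#' Serialize / load a whole interaction dataset as plain-text CSVs
#'
#' Writes `effects.csv`, `mono_yields.csv` and `phylo_dist.csv` under `dir`.
#'
#' @param dataset An `interaction_dataset`.
#' @param dir Directory (created if needed).
#' @return `dir` (write) or the reconstructed dataset (read).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_effects(dataset$effects, file.path(dir, "effects.csv"))
  my <- data.frame(species = rownames(dataset$mono_yields), dataset$mono_yields,
                   check.names = FALSE)
  write_csv_precise(my, file.path(dir, "mono_yields.csv"))
  pd <- data.frame(species = rownames(dataset$phylo_dist), dataset$phylo_dist,
                   check.names = FALSE)
  write_csv_precise(pd, file.path(dir, "phylo_dist.csv"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  eff <- read_effects(file.path(dir, "effects.csv"))
  my <- utils::read.csv(file.path(dir, "mono_yields.csv"), check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(my[, -1, drop = FALSE]); rownames(m) <- my$species
  storage.mode(m) <- "double"
  pd <- utils::read.csv(file.path(dir, "phylo_dist.csv"), check.names = FALSE,
                        stringsAsFactors = FALSE)
  d <- as.matrix(pd[, -1, drop = FALSE]); rownames(d) <- pd$species
  storage.mode(d) <- "double"
  interaction_dataset(eff, m, d)
}
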