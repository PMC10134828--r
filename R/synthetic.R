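# Synthetic coculture-screen generator.
#
# Emulates the statistical structure of a droplet-based pairwise interaction
# screen: 20 species from 2 clades grown alone and in all directed pairs in
# 40 carbon environments, with ~76% negative effects, effects that grow more
# negative with the affected species' monoculture yield, interaction profiles
# conserved within the affecting species' clade, weakly coupled reciprocal
# effects, and ~7% of pair x carbon combinations missing.

#' Configuration for the synthetic coculture screen
#'
#' @param n_species Number of species (default 20).
#' @param n_clades Number of clades in the simulated phylogeny (default 2).
#' @param n_carbons Number of carbon environments (default 40).
#' @param n_replicates Replicate droplets per culture group (default 3).
#' @param yield_phylo_corr Strength in `[0, 1]` of the phylogenetic signal in
#'   monoculture yields: correlation between related species' latent
#'   log-yields decays with distance, scaled by this factor (default 0.7).
#' @param beta_affected Coefficient of the affected species' per-carbon
#'   standardized log monoculture yield on the latent effect (default -0.5;
#'   negative: good growers are inhibited more).
#' @param beta_affecting Same for the affecting species (default 0.15).
#' @param conservation_sd SD of the clade-conserved effect component, shared
#'   by all affecting species of one clade acting on a given species in a
#'   given carbon (default 0.3).
#' @param noise_sd SD of the idiosyncratic latent effect component
#'   (default 0.3).
#' @param target_negative_frac Negative-sign fraction the intercept is
#'   calibrated to by bisection (default 0.76).
#' @param missing_frac Fraction of unordered pair x carbon combinations
#'   deleted uniformly at random (default 0.07).
#' @param replicate_cv Coefficient of variation of multiplicative replicate
#'   noise on yields (default 0.1).
#' @param seed Integer seed; generation is a pure function of (config, seed).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_species = 20, n_clades = 2, n_carbons = 40,
                             n_replicates = 3, yield_phylo_corr = 0.7,
                             beta_affected = -0.5, beta_affecting = 0.15,
                             conservation_sd = 0.3, noise_sd = 0.3,
                             target_negative_frac = 0.76, missing_frac = 0.07,
                             replicate_cv = 0.1, seed = 1) {
  cfg <- list(n_species = n_species, n_clades = n_clades, n_carbons = n_carbons,
              n_replicates = n_replicates, yield_phylo_corr = yield_phylo_corr,
              beta_affected = beta_affected, beta_affecting = beta_affecting,
              conservation_sd = conservation_sd, noise_sd = noise_sd,
              target_negative_frac = target_negative_frac,
              missing_frac = missing_frac, replicate_cv = replicate_cv,
              seed = as.integer(seed))
  stopifnot(cfg$n_species >= 2, cfg$n_clades >= 1, cfg$n_clades <= cfg$n_species,
            cfg$n_carbons >= 1, cfg$n_replicates >= 1,
            cfg$yield_phylo_corr >= 0, cfg$yield_phylo_corr <= 1,
            cfg$conservation_sd >= 0, cfg$noise_sd >= 0,
            cfg$missing_frac >= 0, cfg$missing_frac < 1, cfg$replicate_cv >= 0,
            cfg$target_negative_frac > 0, cfg$target_negative_frac < 1)
  class(cfg) <- "synthetic_config"
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("synthetic_config: %d species / %d clades x %d carbons x %d reps\n",
              x$n_species, x$n_clades, x$n_carbons, x$n_replicates))
  cat(sprintf("  effect model: beta_affected=%.2f beta_affecting=%.2f conservation_sd=%.2f noise_sd=%.2f\n",
              x$beta_affected, x$beta_affecting, x$conservation_sd, x$noise_sd))
  cat(sprintf("  target negative fraction %.2f, missing %.0f%%, replicate CV %.2f, seed %d\n",
              x$target_negative_frac, 100 * x$missing_frac, x$replicate_cv, x$seed))
  invisible(x)
}

species_ids <- function(n) sprintf("sp%02d", seq_len(n))
carbon_ids <- function(n) sprintf("c%02d", seq_len(n))

#' Simulate an ultrametric multi-clade phylogeny and its distance matrix
#'
#' Builds one random coalescent tree per clade (rescaled to a common
#' within-clade height of 0.3), attaches the clades to a root at height 1,
#' and returns patristic distances. Within-clade distances are therefore at
#' most 0.6 while between-clade distances equal 2.
#'
#' @param config A [synthetic_config()].
#' @return Distance matrix with attributes `clade` (named clade assignment)
#'   and `tree` (the `phylo` object).
#' @export
simulate_tree_distances <- function(config) {
  n <- config$n_species; k <- config$n_clades
  if (k > n) stop("more clades than species")
  ids <- species_ids(n)
  sizes <- rep(n %/% k, k); if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1
  clade <- rep(seq_len(k), sizes)
  h_within <- 0.3; h_root <- 1
  with_seed(stage_seed(config$seed, 1), {
    subtrees <- lapply(seq_len(k), function(i) {
      tips <- ids[clade == i]
      if (length(tips) == 1) return(tips)
      tr <- ape::rcoal(length(tips), tip.label = sample(tips))
      depth <- max(ape::node.depth.edgelength(tr))
      tr$edge.length <- tr$edge.length * (h_within / depth)
      tr
    })
    if (k == 1) {
      tree <- subtrees[[1]]
    } else {
      tree <- ape::stree(k, type = "star", tip.label = sprintf("clade%d", seq_len(k)))
      tree$edge.length <- rep(h_root, k)
      for (i in seq_len(k)) {
        sub <- subtrees[[i]]
        wh <- which(tree$tip.label == sprintf("clade%d", i))
        if (is.character(sub)) {
          tree$tip.label[wh] <- sub
        } else {
          tree$edge.length[tree$edge[, 2] == wh] <- h_root - h_within
          tree <- ape::bind.tree(tree, sub, where = wh)
        }
      }
    }
  })
  d <- ape::cophenetic.phylo(tree)
  d <- d[ids, ids]
  names(clade) <- ids
  check_dist_matrix(d)
  structure(d, clade = clade, tree = tree)
}

#' Simulate monoculture growth yields with phylogenetic signal
#'
#' Per carbon, species' latent log-yields are drawn from a multivariate
#' normal whose correlation is `yield_phylo_corr * exp(-d / lambda)` (lambda =
#' half the mean pairwise distance), plus a species-level baseline; yields are
#' the exponentials, hence log-normal and non-negative, with poor growers
#' reaching near-zero yields.
#'
#' @param config A [synthetic_config()].
#' @param phylo_dist Distance matrix from [simulate_tree_distances()].
#' @return Species x carbon yield matrix.
#' @export
simulate_monoculture_yields <- function(config, phylo_dist) {
  n <- config$n_species
  stopifnot(nrow(phylo_dist) == n)
  ids <- rownames(phylo_dist)
  lambda <- mean(phylo_dist[upper.tri(phylo_dist)]) / 2
  if (!is.finite(lambda) || lambda <= 0) lambda <- 1
  K <- exp(-phylo_dist / lambda)
  Sigma <- config$yield_phylo_corr * K + (1 - config$yield_phylo_corr) * diag(n)
  with_seed(stage_seed(config$seed, 2), {
    baseline <- stats::rnorm(n, 0, 0.5)
    L <- MASS::mvrnorm(config$n_carbons, mu = rep(0, n), Sigma = Sigma)
  })
  logy <- t(L) + baseline          # species x carbons
  dimnames(logy) <- list(ids, carbon_ids(config$n_carbons))
  exp(logy)
}

# Latent directed effects for all ordered pairs x carbons, before missingness.
latent_effects <- function(config, phylo_dist, mono_yields) {
  clade <- attr(phylo_dist, "clade")
  if (is.null(clade)) {
    hc <- stats::hclust(stats::as.dist(phylo_dist), method = "average")
    clade <- stats::cutree(hc, k = config$n_clades)
  }
  ids <- rownames(mono_yields); nc <- ncol(mono_yields)
  z <- scale(log(mono_yields))   # per-carbon standardization across species
  z[is.nan(z)] <- 0
  pairs <- expand.grid(affected = ids, affecting = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$affected != pairs$affecting, ]
  grid <- merge(pairs, data.frame(carbon = colnames(mono_yields)), by = NULL)
  with_seed(stage_seed(config$seed, 3), {
    u <- array(stats::rnorm(length(ids) * config$n_clades * nc, 0, config$conservation_sd),
               dim = c(length(ids), config$n_clades, nc),
               dimnames = list(ids, NULL, colnames(mono_yields)))
    eps <- stats::rnorm(nrow(grid), 0, config$noise_sd)
  })
  ia <- match(grid$affected, ids); ib <- match(grid$affecting, ids)
  ic <- match(grid$carbon, colnames(mono_yields))
  core <- config$beta_affected * z[cbind(ia, ic)] +
    config$beta_affecting * z[cbind(ib, ic)] +
    u[cbind(ia, clade[ib], ic)] + eps
  grid$core <- core
  grid
}

# Calibrate the intercept by bisection so the realized negative fraction hits
# the target within tol.
calibrate_intercept <- function(core, target, tol = 0.05) {
  if (diff(range(core)) == 0) {
    warning("constant latent effects: intercept set to 0, sign-fraction target not applicable")
    return(0)
  }
  f <- function(b) mean(core + b < 0)
  lo <- -max(abs(core)) - 10; hi <- max(abs(core)) + 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) hi <- mid else lo <- mid
    if (abs(f(mid) - target) <= 1e-4) break
  }
  b <- (lo + hi) / 2
  if (abs(f(b) - target) > tol)
    stop(sprintf("intercept calibration failed: reached %.3f, target %.3f", f(b), target))
  b
}

#' Simulate replicate-level growth data for the full screen
#'
#' The latent effect of B on A in carbon c is
#' `intercept + beta_affected * z(monoA,c) + beta_affecting * z(monoB,c) +
#' u(A, clade(B), c) + eps`, with `z` the per-carbon standardized log
#' monoculture yield, `u` shared within the affecting species' clade and `eps`
#' idiosyncratic. The intercept is calibrated by bisection to the target
#' negative-sign fraction. Replicate coculture yields are
#' `mono * exp(effect)` with multiplicative log-normal noise (CV =
#' `replicate_cv`); a `missing_frac` fraction of unordered pair x carbon
#' combinations is deleted.
#'
#' @param config A [synthetic_config()].
#' @param phylo_dist,mono_yields Outputs of the two simulators above.
#' @return A replicate-level `growth_table` (mono + co records) with attribute
#'   `truth`: the latent effect table (`affected, affecting, carbon, effect`).
#' @export
simulate_effects <- function(config, phylo_dist, mono_yields) {
  grid <- latent_effects(config, phylo_dist, mono_yields)
  with_seed(stage_seed(config$seed, 4), {
    # uniform missingness over unordered pair x carbon combos
    a <- pmin(grid$affected, grid$affecting); b <- pmax(grid$affected, grid$affecting)
    combo <- paste(a, b, grid$carbon, sep = "\r")
    uc <- unique(combo)
    drop <- uc[stats::runif(length(uc)) < config$missing_frac]
    grid <- grid[!(combo %in% drop), , drop = FALSE]
    intercept <- calibrate_intercept(grid$core, config$target_negative_frac)
    grid$effect <- grid$core + intercept
    ids <- rownames(mono_yields)
    noise_factor <- function(n) {
      if (config$replicate_cv == 0) return(rep(1, n))
      sdlog <- sqrt(log(1 + config$replicate_cv^2))
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    reps <- seq_len(config$n_replicates)
    # monoculture records
    mono_df <- expand.grid(species = ids, carbon = colnames(mono_yields),
                           replicate = reps, stringsAsFactors = FALSE)
    mono_mean <- mono_yields[cbind(match(mono_df$species, ids),
                                   match(mono_df$carbon, colnames(mono_yields)))]
    mono_df <- data.frame(species = mono_df$species, partner = MONO,
                          carbon = mono_df$carbon, replicate = mono_df$replicate,
                          yield = mono_mean * noise_factor(nrow(mono_df)),
                          stringsAsFactors = FALSE)
    # coculture records: yield of the affected species in each directed pair
    co_df <- grid[rep(seq_len(nrow(grid)), each = config$n_replicates), ]
    co_df$replicate <- rep(reps, nrow(grid))
    co_mean <- mono_yields[cbind(match(co_df$affected, ids),
                                 match(co_df$carbon, colnames(mono_yields)))] *
      exp(co_df$effect)
    co_df <- data.frame(species = co_df$affected, partner = co_df$affecting,
                        carbon = co_df$carbon, replicate = co_df$replicate,
                        yield = co_mean * noise_factor(nrow(co_df)),
                        stringsAsFactors = FALSE)
  })
  out <- as_growth_table(rbind(mono_df, co_df))
  truth <- grid[, c("affected", "affecting", "carbon", "effect")]
  truth <- truth[order(truth$affected, truth$affecting, truth$carbon), ]
  rownames(truth) <- NULL
  attr(out, "truth") <- truth
  attr(out, "intercept") <- intercept
  out
}

#' Generate a complete synthetic interaction dataset
#'
#' Runs the tree, yield and effect simulators and pushes the replicate-level
#' growth table through the standard dataset pipeline (replicate filter +
#' effect computation), so the synthetic path exercises exactly the code used
#' for real screens.
#'
#' @param config A [synthetic_config()].
#' @param min_reps Replicate filter threshold applied downstream (default 3).
#' @return A list of class `synthetic_screen`: `dataset`
#'   (`interaction_dataset`), `growth` (replicate table), `truth` (latent
#'   effects), `phylo_dist`, `tree`, `clade`, `config`.
#' @export
simulate_dataset <- function(config = synthetic_config(), min_reps = 3) {
  pd <- simulate_tree_distances(config)
  my <- simulate_monoculture_yields(config, pd)
  growth <- simulate_effects(config, pd, my)
  d <- unclass(pd); attributes(d) <- attributes(d)[c("dim", "dimnames")]
  ds <- suppressMessages(build_dataset(growth, d, min_reps = min_reps))
  structure(list(dataset = ds, growth = growth, truth = attr(growth, "truth"),
                 phylo_dist = d, tree = attr(pd, "tree"),
                 clade = attr(pd, "clade"), config = config),
            class = "synthetic_screen")
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat("synthetic_screen (seed", x$config$seed, ")\n")
  print(x$dataset)
  invisible(x)
}

#' Write a synthetic screen to disk
#'
#' Writes `growth.csv` (replicate-level table), `phylo_dist.csv`,
#' `tree.nwk` and `truth.csv` (latent effects, for recovery tests).
#'
#' @param screen A `synthetic_screen`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic_screen <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_precise(screen$growth, file.path(dir, "growth.csv"))
  pd <- data.frame(species = rownames(screen$phylo_dist), screen$phylo_dist,
                   check.names = FALSE)
  write_csv_precise(pd, file.path(dir, "phylo_dist.csv"))
  ape::write.tree(screen$tree, file.path(dir, "tree.nwk"))
  write_csv_precise(screen$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
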