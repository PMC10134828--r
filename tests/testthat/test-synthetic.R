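# Generator contracts: determinism, planted phylogenetic/clade structure,
# effect-model recovery, and calibration of the sign imbalance.

test_that("tree distances are valid, clade-structured, and deterministic", {
  cfg <- synthetic_config(n_species = 12, n_clades = 2, seed = 3)
  d1 <- simulate_tree_distances(cfg)
  d2 <- simulate_tree_distances(cfg)
  expect_identical(unclass(d1)[, ], unclass(d2)[, ])
  cl <- attr(d1, "clade")
  same <- outer(cl, cl, "==") & upper.tri(d1)
  diff <- outer(cl, cl, "!=") & upper.tri(d1)
  expect_lt(max(d1[same]), min(d1[diff]))
  # triangle inequality
  n <- nrow(d1)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(d1[i, j], d1[i, k] + d1[k, j] + 1e-12)
  # smallest case
  d <- simulate_tree_distances(synthetic_config(n_species = 2, n_clades = 2, seed = 1))
  expect_equal(dim(d), c(2, 2))
  expect_gt(d[1, 2], 0)
  expect_equal(diag(d), c(sp01 = 0, sp02 = 0))
  expect_error(simulate_tree_distances(synthetic_config(n_species = 3, n_clades = 4)))
})

test_that("monoculture yields carry the configured phylogenetic signal", {
  sister_vs_distant <- function(rho, seed) {
    cfg <- synthetic_config(n_species = 8, n_carbons = 40,
                            yield_phylo_corr = rho, seed = seed)
    d <- simulate_tree_distances(cfg)
    y <- simulate_monoculture_yields(cfg, d)
    dd <- unclass(d); diag(dd) <- Inf
    sis <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    far <- which(dd == max(dd[is.finite(dd)]), arr.ind = TRUE)[1, ]
    c(sister = cor(y[sis[1], ], y[sis[2], ]),
      distant = cor(y[far[1], ], y[far[2], ]))
  }
  # independence limit: sister correlation is near zero on average
  r0 <- sapply(1:20, function(s) sister_vs_distant(0, s)["sister"])
  expect_lt(mean(abs(r0)), 0.2)
  # strong signal: sisters beat distant pairs in at least 9/10 seeds
  wins <- sapply(1:10, function(s) {
    r <- sister_vs_distant(0.9, s); r["sister"] > r["distant"]
  })
  expect_gte(sum(wins), 9)
  # determinism
  cfg <- synthetic_config(seed = 5)
  d <- simulate_tree_distances(cfg)
  expect_identical(simulate_monoculture_yields(cfg, d),
                   simulate_monoculture_yields(cfg, d))
})

test_that("degenerate effect model collapses to the intercept exactly", {
  cfg <- synthetic_config(n_species = 5, n_carbons = 4,
                          beta_affected = 0, beta_affecting = 0,
                          conservation_sd = 0, noise_sd = 0, replicate_cv = 0,
                          missing_frac = 0, target_negative_frac = 0.76, seed = 8)
  d <- simulate_tree_distances(cfg)
  y <- simulate_monoculture_yields(cfg, d)
  expect_warning(gt <- simulate_effects(cfg, d, y), "constant latent effects")
  truth <- attr(gt, "truth")
  expect_equal(length(unique(round(truth$effect, 12))), 1)
  expect_equal(truth$effect[1], attr(gt, "intercept"))
  # recovered effects through the dataset path equal the intercept too
  eff <- suppressMessages(compute_effects(filter_min_replicates(gt, 3)))
  expect_lt(max(abs(eff$effect - attr(gt, "intercept"))), 1e-12)
})

test_that("generation is a pure function of config and seed", {
  cfg <- synthetic_config(n_species = 8, n_carbons = 10, seed = 21)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$dataset$effects, s2$dataset$effects)
  expect_identical(s1$growth$yield, s2$growth$yield)
})

test_that("noiseless replicates pass through the dataset path exactly", {
  s <- small_screen(seed = 3, replicate_cv = 0)
  m <- merge(s$dataset$effects, s$truth, by = c("affected", "affecting", "carbon"))
  expect_equal(nrow(m), nrow(s$dataset$effects))
  expect_lt(max(abs(m$effect.x - m$effect.y)), 1e-12)
})

test_that("effect-model coefficients are recoverable by regression", {
  cfg <- synthetic_config(seed = 17)
  d <- simulate_tree_distances(cfg)
  y <- simulate_monoculture_yields(cfg, d)
  gt <- simulate_effects(cfg, d, y)
  truth <- attr(gt, "truth")
  z <- scale(log(y))
  df <- data.frame(
    eff = truth$effect,
    za = z[cbind(truth$affected, truth$carbon)],
    zb = z[cbind(truth$affecting, truth$carbon)])
  fit <- lm(eff ~ za + zb, data = df)
  est <- coef(summary(fit))
  expect_lt(abs(est["za", "Estimate"] - cfg$beta_affected), 2 * est["za", "Std. Error"] + 0.02)
  expect_lt(abs(est["zb", "Estimate"] - cfg$beta_affecting), 2 * est["zb", "Std. Error"] + 0.02)
})

test_that("missingness removes whole pair-carbon combinations at the target rate", {
  s <- simulate_dataset(synthetic_config(seed = 9))
  eff <- s$dataset$effects
  n_expected <- 20 * 19 * 40
  frac <- 1 - nrow(eff) / n_expected
  expect_gt(frac, 0.03); expect_lt(frac, 0.12)
  # both directions of a pair are present or absent together
  key <- paste(pmin(eff$affected, eff$affecting),
               pmax(eff$affected, eff$affecting), eff$carbon)
  expect_true(all(table(key) == 2))
})

test_that("synthetic screens serialize to plain-text files", {
  s <- small_screen(seed = 5)
  dir <- withr::local_tempdir()
  write_synthetic_screen(s, dir)
  expect_true(all(file.exists(file.path(dir, c("growth.csv", "phylo_dist.csv",
                                               "tree.nwk", "truth.csv")))))
  gt <- read_growth_table(file.path(dir, "growth.csv"))
  expect_identical(gt$yield, s$growth$yield)
})
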