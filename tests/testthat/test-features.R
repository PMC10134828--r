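# PCA feature builders, held-out-carbon projection, metabolic distance, and
# feature-table assembly.

test_that("phylogenetic PCs match an eigendecomposition oracle", {
  # two clades at large separation: PC1 separates them
  sp <- paste0("s", 1:6)
  d <- matrix(10, 6, 6, dimnames = list(sp, sp))
  # distinct within-clade distances keep the eigenvalues non-degenerate
  d[1:3, 1:3] <- c(0, .4, .7, .4, 0, .5, .7, .5, 0)
  d[4:6, 4:6] <- c(0, .3, .8, .3, 0, .6, .8, .6, 0)
  diag(d) <- 0
  pp <- phylo_pcs(d)
  gap <- abs(mean(pp$scores[1:3, 1]) - mean(pp$scores[4:6, 1]))
  spread <- max(diff(range(pp$scores[1:3, 1])), diff(range(pp$scores[4:6, 1])))
  expect_gt(gap, spread)
  # explained variance equals top eigenvalues over the trace
  Xc <- scale(d, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(d) - 1))$values
  expect_equal(pp$explained_var, ev[1:2] / sum(ev), tolerance = 1e-9)
  # scores match the oracle projection up to the pinned sign
  expect_equal(abs(unname(pp$scores)),
               abs(unname(Xc %*% eigen(crossprod(Xc))$vectors[, 1:2])),
               tolerance = 1e-8)
  # degenerate case: no variance, all coordinates zero
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(phylo_pcs(z)$scores == 0))
  # non-symmetric input is rejected
  bad <- d; bad[1, 2] <- 99
  expect_error(phylo_pcs(bad), "symmetric")
})

test_that("carbon PCs are profile PCA with a reusable projection", {
  set.seed(1)
  y <- matrix(rexp(8 * 6), 8, 6, dimnames = list(paste0("s", 1:8), paste0("c", 1:6)))
  cp <- carbon_pcs(y, 4)
  # oracle eigendecomposition of the carbon-profile covariance
  M <- t(y); Mc <- scale(M, center = TRUE, scale = FALSE)
  eg <- eigen(crossprod(Mc))
  expect_equal(abs(unname(cp$scores)), abs(unname(Mc %*% eg$vectors[, 1:4])),
               tolerance = 1e-9)
  # duplicate profiles map to the same coordinates
  y2 <- cbind(y, c7 = y[, "c3"])
  cp2 <- carbon_pcs(y2, 4)
  expect_equal(cp2$scores["c7", ], cp2$scores["c3", ], tolerance = 1e-9)
  # rank limit: a rank-1 matrix cannot yield 4 components
  r1 <- outer(1:8, 1:6) * 1.0
  dimnames(r1) <- dimnames(y)
  expect_error(carbon_pcs(r1, 4), "rank")
  expect_error(carbon_pcs(y[, 1:4], 4), "carbons")
})

test_that("held-out carbon projection reproduces fitted coordinates", {
  set.seed(2)
  y <- matrix(rexp(10 * 8), 10, 8,
              dimnames = list(paste0("s", 1:10), paste0("c", 1:8)))
  cp <- carbon_pcs(y, 4)
  # idempotence on every training carbon
  for (cb in colnames(y))
    expect_equal(project_heldout_carbon(cp, y[, cb]), cp$scores[cb, ],
                 tolerance = 1e-9)
  # the mean profile projects to the origin
  expect_equal(unname(project_heldout_carbon(cp, rowMeans(y))),
               rep(0, 4), tolerance = 1e-9)
  # generic profile matches hand linear algebra
  prof <- y[, 1] * 0.3 + rexp(10)
  names(prof) <- rownames(y)
  expect_equal(project_heldout_carbon(cp, prof),
               drop(t(cp$rotation) %*% (prof - cp$center)), tolerance = 1e-12)
  expect_error(project_heldout_carbon(cp, prof[1:5]), "dimension")
})

test_that("metabolic distance is the Euclidean profile distance and a metric", {
  y <- rbind(a = c(1, 2, 2), b = c(3, 0, 1), c = c(1, 2, 2), d = c(1, 2, 5))
  colnames(y) <- paste0("c", 1:3)
  expect_equal(metabolic_distance(y, "a", "b"), 3)
  expect_equal(metabolic_distance(y, "a", "c"), 0)
  expect_equal(metabolic_distance(y, "a", "d"), 3)
  expect_error(metabolic_distance(y, "a", "zz"), "unknown")
  # metric properties on random imputed profiles
  set.seed(3)
  for (rep in 1:20) {
    m <- matrix(rexp(5 * 6), 5, 6, dimnames = list(paste0("s", 1:5), paste0("c", 1:6)))
    m[sample(length(m), 4)] <- NA
    dm <- as.matrix(dist(growthfx:::impute_mono(m)))
    expect_equal(dm, t(dm))
    expect_true(all(diag(dm) == 0))
    for (i in 1:5) for (j in 1:5) for (k in 1:5)
      expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-9)
  }
})

test_that("assembled feature tables have the documented mandatory schema", {
  s <- small_screen()
  ft <- assemble_features(s$dataset)
  expect_s3_class(ft, "feature_table")
  expect_equal(feature_columns(ft),
               c("mono_affected", "mono_affecting", "metab_dist",
                 "phylo_pc1_affected", "phylo_pc1_affecting",
                 "phylo_pc2_affected", "phylo_pc2_affecting",
                 paste0("carbon_pc", 1:4)))
  expect_equal(length(feature_columns(ft)), 11)
  expect_false(anyNA(ft[, feature_columns(ft)]))
  # unique row keys; carbon PCs constant within carbon
  expect_false(anyDuplicated(ft[, c("affected", "affecting", "carbon")]) > 0)
  pc_by_carbon <- tapply(ft$carbon_pc1, ft$carbon, function(v) diff(range(v)))
  expect_true(all(pc_by_carbon == 0))
})

test_that("feature options toggle blocks and join the reciprocal effect", {
  s <- small_screen()
  ft <- assemble_features(s$dataset, feature_options(drop_monoculture_features = TRUE))
  expect_false(any(c("mono_affected", "mono_affecting", "metab_dist") %in%
                     feature_columns(ft)))
  ft2 <- assemble_features(s$dataset, feature_options(reciprocal_effect = TRUE))
  eff <- s$dataset$effects
  key <- paste(eff$affected, eff$affecting, eff$carbon)
  i <- match(paste(ft2$affecting, ft2$affected, ft2$carbon), key)
  expect_equal(ft2$reciprocal_effect, eff$effect[i])
  # optional blocks demand their inputs
  expect_error(assemble_features(s$dataset,
                                 feature_options(chemistry = data.frame(x = 1))),
               "chemistry")
  # carbon one-hot adds one indicator per carbon
  ft3 <- assemble_features(s$dataset, feature_options(carbon_onehot = TRUE))
  expect_equal(sum(grepl("^carbon_is_", feature_columns(ft3))), 12)
})

test_that("feature tables round-trip through CSV", {
  s <- small_screen()
  ft <- assemble_features(s$dataset)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(ft, path)
  back <- read_features(path)
  expect_identical(back$effect, ft$effect)
  expect_equal(feature_columns(back), feature_columns(ft))
  expect_identical(back$carbon_pc1, ft$carbon_pc1)
})
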