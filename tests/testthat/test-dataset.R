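# Growth-table handling and the log-ratio effect statistic.

test_that("replicate filter keeps exactly the groups with enough replicates", {
  # groups of sizes 1, 2, 3, 4 -> only the 3- and 4-replicate groups survive
  gt <- as_growth_table(data.frame(
    species = c("A", "B", "B", "C", "C", "C", "D", "D", "D", "D"),
    partner = "MONO", carbon = "glc",
    replicate = c(1, 1:2, 1:3, 1:4), yield = 1))
  out <- suppressMessages(filter_min_replicates(gt, 3))
  expect_equal(nrow(out), 7)
  expect_setequal(unique(out$species), c("C", "D"))
  # min_reps = 1 is a no-op
  expect_equal(nrow(suppressMessages(filter_min_replicates(gt, 1))), 10)
  # a 2-replicate group is removed at the default threshold
  expect_false("B" %in% suppressMessages(filter_min_replicates(gt, 3))$species)
  expect_error(as_growth_table(gt[0, ]), "empty growth table")
})

test_that("effects are log ratios of mean coculture to mean monoculture yield", {
  eff <- suppressMessages(compute_effects(filter_min_replicates(toy_growth(), 2)))
  e_ab <- eff[eff$affected == "A" & eff$affecting == "B", ]
  expect_equal(e_ab$effect, log(3 / 6))
  expect_equal(e_ab$sign, "negative")
  # equal yields give a zero effect, a factor of e gives exactly 1
  m <- 7.3
  gt <- as_growth_table(data.frame(
    species = c("A", "A", "B", "B", "A", "A", "A", "A"),
    partner = c("MONO", "MONO", "MONO", "MONO", "B", "B", "C", "C"),
    carbon = "x", replicate = rep(1:2, 4),
    yield = c(m, m, 1, 1, m, m, exp(1) * m, exp(1) * m)))
  gt <- rbind(gt, data.frame(species = "C", partner = "MONO", carbon = "x",
                             replicate = 1:2, yield = 1))
  eff2 <- compute_effects(as_growth_table(gt))
  expect_equal(eff2$effect[eff2$affecting == "B"], 0)
  expect_equal(eff2$effect[eff2$affecting == "C"], 1)
})

test_that("zero or missing monoculture references drop records with a warning", {
  gt <- as_growth_table(data.frame(
    species = c("A", "A", "B", "B", "A", "A"),
    partner = c("MONO", "MONO", "MONO", "MONO", "B", "B"),
    carbon = c("x", "x", "y", "y", "x", "x"),   # B has no mono in carbon x
    replicate = rep(1:2, 3), yield = c(5, 5, 3, 3, 4, 4)))
  gt2 <- rbind(gt, data.frame(species = "B", partner = "A", carbon = "x",
                              replicate = 1:2, yield = 1))
  expect_warning(eff <- compute_effects(as_growth_table(gt2)), "monoculture")
  expect_equal(nrow(eff), 1)  # only A <- B survives
})

test_that("effect computation is invariant to replicate order", {
  gt <- four_species_growth()
  shuf <- gt[rev(seq_len(nrow(gt))), ]
  expect_equal(compute_effects(as_growth_table(shuf)), compute_effects(gt))
})

test_that("pair types follow the sign pair", {
  e <- function(a, b, v) data.frame(affected = a, affecting = b, carbon = "c",
                                    effect = v,
                                    sign = ifelse(v > 0, "positive", "negative"))
  expect_equal(label_pair_type(e("A", "B", -0.5), e("B", "A", -0.2)), "competition")
  expect_equal(label_pair_type(e("A", "B", 0.3), e("B", "A", 0.3)), "mutualism")
  expect_equal(label_pair_type(e("A", "B", 0.3), e("B", "A", -0.1)), "parasitism")
  expect_error(label_pair_type(e("A", "B", 1), e("C", "A", 1)), "directions")
})

test_that("dataset round-trips through CSV bit-exactly", {
  ds <- build_dataset(four_species_growth(), four_species_dist()) |>
    suppressMessages()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$effects$effect, ds$effects$effect)
  expect_identical(back$mono_yields, ds$mono_yields)
  expect_identical(back$phylo_dist, ds$phylo_dist)
})

test_that("exp(effect) times the monoculture mean recovers the coculture mean", {
  s <- small_screen(seed = 4)
  ds <- s$dataset
  gt <- s$growth
  co <- gt[gt$partner != "MONO", ]
  agg <- stats::aggregate(yield ~ species + partner + carbon, data = co, FUN = mean)
  key <- paste(agg$species, agg$partner, agg$carbon)
  idx <- match(paste(ds$effects$affected, ds$effects$affecting, ds$effects$carbon), key)
  mono <- ds$mono_yields[cbind(ds$effects$affected, ds$effects$carbon)]
  expect_lt(max(abs(exp(ds$effects$effect) * mono - agg$yield[idx])), 1e-9)
})

test_that("phylogeny input accepts square CSV and newick equivalently", {
  s <- small_screen(seed = 6)
  dir <- withr::local_tempdir()
  nwk <- file.path(dir, "tree.nwk")
  ape::write.tree(s$tree, nwk)
  d_tree <- read_phylo_dist(nwk)
  expect_equal(d_tree, s$phylo_dist[rownames(d_tree), colnames(d_tree)],
               tolerance = 1e-8)
  csv <- file.path(dir, "dist.csv")
  utils::write.csv(data.frame(species = rownames(s$phylo_dist), s$phylo_dist),
                   csv, row.names = FALSE)
  # read back with first column as rownames
  d_csv <- read_phylo_dist(csv)
  expect_equal(unname(d_csv), unname(s$phylo_dist), tolerance = 1e-12)
})
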