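# Hand-built fixtures and independent oracles shared across tests.

# Replicate-level growth table for 2 species x 1 carbon with known arithmetic:
# effect(A <- B) = ln(mean(2,4) / mean(6,6)) = ln(3/6).
toy_growth <- function() {
  as_growth_table(data.frame(
    species = c(rep("A", 2), rep("B", 3), rep("A", 2), rep("B", 3)),
    partner = c(rep("MONO", 5), rep("B", 2), rep("A", 3)),
    carbon = "glc",
    replicate = c(1:2, 1:3, 1:2, 1:3),
    yield = c(6, 6, 10, 10, 10, 2, 4, 12, 9, 9)))
}

# Four-species fixture with all four directed pairs in one carbon, chosen so
# every effect is a clean log ratio.
four_species_growth <- function() {
  rows <- list()
  mono <- c(A = 10, B = 20, C = 5, D = 8)
  co <- list(c("A", "B", 5), c("B", "A", 40), c("A", "C", 10), c("C", "A", 15),
             c("B", "C", 10), c("C", "B", 5), c("A", "D", 20), c("D", "A", 4))
  for (s in names(mono))
    rows[[length(rows) + 1]] <- data.frame(species = s, partner = "MONO",
                                           carbon = "glc", replicate = 1:3,
                                           yield = mono[[s]])
  for (p in co)
    rows[[length(rows) + 1]] <- data.frame(species = p[1], partner = p[2],
                                           carbon = "glc", replicate = 1:3,
                                           yield = as.numeric(p[3]))
  as_growth_table(do.call(rbind, rows))
}

four_species_dist <- function() {
  sp <- c("A", "B", "C", "D")
  d <- matrix(c(0, 1, 4, 4,
                1, 0, 4, 4,
                4, 4, 0, 1.5,
                4, 4, 1.5, 0), 4, 4, dimnames = list(sp, sp))
  d
}

# Small synthetic screen reused by several tests (cheap to build).
small_screen <- function(seed = 2, ...) {
  simulate_dataset(synthetic_config(n_species = 10, n_carbons = 12,
                                    seed = seed, ...))
}

# Independent confusion-matrix oracle (table-based, unlike the package's
# vectorized counts).
oracle_classification <- function(y_true, y_pred) {
  tab <- table(factor(y_true, c("negative", "positive")),
               factor(y_pred, c("negative", "positive")))
  tp <- tab["positive", "positive"]; tn <- tab["negative", "negative"]
  fp <- tab["negative", "positive"]; fn <- tab["positive", "negative"]
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  list(accuracy = (tp + tn) / length(y_true),
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / den,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

oracle_regression <- function(y_true, y_pred) {
  rmse <- sqrt(sum((y_true - y_pred)^2) / length(y_true))
  list(rmse = rmse,
       nrmse = rmse / sqrt(sum((y_true - mean(y_true))^2) / length(y_true)),
       r2 = 1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2))
}

# Brute-force optimal single-feature threshold accuracy over all midpoints,
# +/- infinity, and both directions.
oracle_threshold_accuracy <- function(x, y) {
  v <- sort(unique(x))
  cand <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  best <- 0
  for (t in cand) for (ge_lab in c("negative", "positive")) {
    lt_lab <- setdiff(c("negative", "positive"), ge_lab)
    acc <- mean(ifelse(x >= t, ge_lab, lt_lab) == y)
    best <- max(best, acc)
  }
  best
}

# Exhaustive MIC oracle for tiny n: enumerate every pair of cut subsets with
# at most B cells, score normalized mutual information directly from the
# contingency table (independent of the package's enumeration code).
oracle_mic_tiny <- function(x, y, alpha = 0.6) {
  n <- length(x)
  B <- max(4, n^alpha)
  mids <- function(v) { sv <- sort(unique(v)); (sv[-1] + sv[-length(sv)]) / 2 }
  all_subsets <- function(v, kmax) {
    out <- list()
    for (k in seq_len(min(length(v), kmax)))
      out <- c(out, utils::combn(v, k, simplify = FALSE))
    out
  }
  nmi <- function(cx, cy) {
    gx <- findInterval(x, cx); gy <- findInterval(y, cy)
    tab <- table(gx, gy) / n
    px <- rowSums(tab); py <- colSums(tab)
    I <- sum(tab[tab > 0] * log(tab[tab > 0])) -
      sum(px * log(px)) - sum(py * log(py))
    I / log(min(length(cx), length(cy)) + 1)
  }
  best <- 0
  for (cx in all_subsets(mids(x), floor(B / 2) - 1)) {
    maxy <- floor(B / (length(cx) + 1)) - 1
    if (maxy < 1) next
    for (cy in all_subsets(mids(y), maxy))
      best <- max(best, nmi(cx, cy))
  }
  best
}
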