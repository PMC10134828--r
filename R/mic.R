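# Maximal information coefficient: a normalized-mutual-information measure of
# general bivariate dependence, 0 for independent variables and 1 for
# noiseless functional relationships.

#' Maximal information coefficient of two variables
#'
#' Maximizes, over all grid partitions of the plane with at most
#' `B(n) = max(4, n^alpha)` cells (both dimensions >= 2), the mutual
#' information of the induced discretization normalized by
#' `log(min(columns, rows))`. The default method equipartitions one axis and
#' optimizes the other by dynamic programming over clump boundaries (with at
#' most `c * columns` clumps), in both orientations; `method = "exact"`
#' enumerates every admissible grid and is available for n <= 12 (it is the
#' oracle the approximation is tested against). Rank-based, hence invariant
#' to strictly monotone transformations of either variable; deterministic.
#'
#' @param x,y Numeric vectors (pairs with NA dropped).
#' @param alpha Grid-budget exponent (default 0.6).
#' @param c Clump budget multiplier for the DP (default 15).
#' @param method `"approx"` (default) or `"exact"`.
#' @return MIC in `[0, 1]`; 0 with a warning if either variable is constant.
#' @export
mic <- function(x, y, alpha = 0.6, c = 15, method = c("approx", "exact")) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  n <- length(x)
  if (n < 2) stop("need at least two complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant variable: MIC is 0")
    return(0)
  }
  B <- max(4, n^alpha)
  if (method == "approx") return(mic_approx_cpp(x, y, B, as.integer(c)))
  if (n > 12) stop("exact MIC enumeration is limited to n <= 12")
  mic_exact(x, y, B)
}

# Exhaustive enumeration over all cut placements on both axes (tiny n only).
mic_exact <- function(x, y, B) {
  cuts_along <- function(v) {
    sv <- sort(unique(v))
    if (length(sv) < 2) return(numeric(0))
    (sv[-1] + sv[-length(sv)]) / 2
  }
  cx <- cuts_along(x); cy <- cuts_along(y)
  subsets <- function(cand, max_cells) {
    out <- list()
    kmax <- min(length(cand), max_cells - 1)
    for (k in 1:kmax) {
      cmb <- utils::combn(cand, k, simplify = FALSE)
      out <- c(out, cmb)
    }
    out
  }
  best <- 0
  max_cx <- floor(B / 2)
  sx <- subsets(cx, max_cx)
  for (scx in sx) {
    ncx <- length(scx) + 1
    max_cy <- floor(B / ncx)
    if (max_cy < 2) next
    for (scy in subsets(cy, max_cy)) {
      ncy <- length(scy) + 1
      gx <- findInterval(x, scx)
      gy <- findInterval(y, scy)
      tab <- table(gx, gy)
      p <- tab / sum(tab)
      px <- rowSums(p); py <- colSums(p)
      I <- sum(p[p > 0] * log(p[p > 0])) -
        sum(px[px > 0] * log(px[px > 0])) - sum(py[py > 0] * log(py[py > 0]))
      m <- I / log(min(ncx, ncy))
      if (m > best) best <- m
    }
  }
  min(max(best, 0), 1)
}

#' Dependence between reciprocal effects
#'
#' Pairs every two-way interaction's directed effects (effect of B on A,
#' effect of A on B, per carbon) and returns their MIC, quantifying how
#' informative one direction is about the other.
#'
#' @param effects Effect records (as in an `interaction_dataset`).
#' @param ... Passed on to [mic()].
#' @return List of class `reciprocal_dependence`: `mic`, `n_pairs`, and the
#'   paired effect data.frame (`effect_ab`, `effect_ba`).
#' @export
reciprocal_dependence <- function(effects, ...) {
  a <- pmin(effects$affected, effects$affecting)
  b <- pmax(effects$affected, effects$affecting)
  key <- paste(a, b, effects$carbon, sep = "\r")
  is_ab <- effects$affected == a
  e_ab <- effects$effect[is_ab]; k_ab <- key[is_ab]
  e_ba <- effects$effect[!is_ab]; k_ba <- key[!is_ab]
  m <- match(k_ab, k_ba)
  ok <- !is.na(m)
  pairs <- data.frame(pair_a = a[is_ab][ok], pair_b = b[is_ab][ok],
                      carbon = effects$carbon[is_ab][ok],
                      effect_ab = e_ab[ok], effect_ba = e_ba[m[ok]],
                      stringsAsFactors = FALSE)
  if (nrow(pairs) < 25) stop("need at least 25 complete reciprocal pairs")
  structure(list(mic = mic(pairs$effect_ab, pairs$effect_ba, ...),
                 n_pairs = nrow(pairs), pairs = pairs),
            class = "reciprocal_dependence")
}

#' @export
print.reciprocal_dependence <- function(x, ...) {
  cat(sprintf("reciprocal effects: MIC %.3f over %d pairs (Pearson r %.3f)\n",
              x$mic, x$n_pairs, stats::cor(x$pairs$effect_ab, x$pairs$effect_ba)))
  invisible(x)
}
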