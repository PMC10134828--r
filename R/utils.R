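#' @useDynLib growthfx, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

# Sentinel partner token marking monoculture records in long-format growth tables.
MONO <- "MONO"

#' Derive a stage-specific seed from a global seed
#'
#' A single experiment seed fans out to per-stage seeds by a fixed counter
#' scheme (`seed * 113 + stage` modulo 2^31 - 1), so any stage can be re-run
#' in isolation and reproduce its in-pipeline behaviour.
#'
#' @param seed Integer global seed.
#' @param stage Integer stage counter (>= 0).
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 113 + stage) %% (2^31 - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run an expression under a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Full-precision numeric formatting so CSV round-trips are bit exact.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
  out
}

# Write a data.frame as headered CSV with full-precision numeric columns.
write_csv_precise <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]])) df2[[j]] <- fmt_num(df2[[j]])
  }
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
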