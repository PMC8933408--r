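# Internal helpers shared across the pipeline.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Pearson correlation with a defined value for degenerate input
#'
#' Ordinary Pearson correlation, except that whenever either vector has zero
#' variance the correlation is defined as 0 (with a warning) rather than
#' `NA`. Ranking and classification steps throughout the package compare
#' correlations; a degenerate vector must not poison those comparisons.
#'
#' @param x,y Numeric vectors of equal length.
#' @param warn Emit a warning when the zero-variance rule fires (default TRUE).
#' @return A single correlation value in `[-1, 1]`.
#' @export
cor_safe <- function(x, y, warn = TRUE) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) {
    if (warn) warning("zero-variance input: correlation defined as 0")
    return(0)
  }
  stats::cor(x, y)
}

# Column-wise correlations of each column of `M` with each column of `C`
# (rows are observations).  Zero-variance columns yield correlation 0.
cor_cols_safe <- function(M, C) {
  M <- as.matrix(M); C <- as.matrix(C)
  sm <- apply(M, 2, stats::sd)
  sc <- apply(C, 2, stats::sd)
  out <- matrix(0, ncol(M), ncol(C))
  ok_m <- sm > 0
  ok_c <- sc > 0
  if (any(ok_m) && any(ok_c)) {
    out[ok_m, ok_c] <- stats::cor(M[, ok_m, drop = FALSE], C[, ok_c, drop = FALSE])
  }
  out
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
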