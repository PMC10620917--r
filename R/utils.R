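# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Shannon entropy of a composition vector
#'
#' `H(p) = -sum(p * log(p, base))`, with the convention `0 * log(0) = 0`.
#' Entropy is nonnegative; the natural logarithm is the default base.
#'
#' @param p numeric vector of nonnegative proportions (need not be normalized;
#'   it is renormalized to sum 1 unless it sums to 0).
#' @param base logarithm base (default `exp(1)`; use 2 for bits).
#' @return nonnegative scalar entropy.
#' @examples
#' shannonEntropy(c(0.5, 0.5), base = 2) # 1 bit
#' shannonEntropy(c(1, 0))               # 0
#' @export
shannonEntropy <- function(p, base = exp(1)) {
  if (any(p < -1e-12)) stop("entropy requires nonnegative proportions")
  p <- pmax(p, 0)
  s <- sum(p)
  if (s == 0) return(0)
  p <- p[p > 0] / s
  -sum(p * log(p, base = base))
}

# Check a vector lies on the probability simplex.
assertSimplex <- function(p, name = "composition", tol = 1e-6) {
  if (any(p < -1e-12)) stop(name, " has negative entries")
  if (abs(sum(p) - 1) > tol) stop(name, " does not sum to 1 (sum = ", format(sum(p)), ")")
  invisible(TRUE)
}

# Row-major tile index for 0-based (row, col).
tileIndex <- function(row, col, nCols) row * nCols + col + 1L

# Tile indices (1-based, row-major) covered by a half-open tile window.
windowTileIndices <- function(row0, col0, heightTiles, widthTiles, nCols) {
  rows <- seq.int(row0, row0 + heightTiles - 1L)
  cols <- seq.int(col0, col0 + widthTiles - 1L)
  as.integer(outer(rows * nCols, cols, "+") + 1L)
}

# Do two half-open tile windows overlap?
windowsOverlap <- function(w1, w2) {
  rOver <- w1$row0 < w2$row0 + w2$heightTiles && w2$row0 < w1$row0 + w1$heightTiles
  cOver <- w1$col0 < w2$col0 + w2$widthTiles && w2$col0 < w1$col0 + w1$widthTiles
  rOver && cOver
}
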