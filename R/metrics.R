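# selection_metrics: MSE / Jensen-Shannon divergence / mean ROI entropy.

#' Mean squared error between two composition vectors
#'
#' `MSE = (1/n) * sum((R_i - W0_i)^2)` over the n clusters.
#'
#' @param R combined composition of the selected ROIs.
#' @param W0 WSI composition (same length).
#' @return nonnegative scalar.
#' @examples
#' compositionMSE(c(0.6, 0.4), c(0.5, 0.5)) # 0.01
#' @export
compositionMSE <- function(R, W0) {
  if (length(R) != length(W0)) stop("R and W0 must have equal length")
  if (length(R) < 1L) stop("empty composition")
  mean((R - W0)^2)
}

# Kullback-Leibler divergence KL(p || q) in the given base; 0*log(0) = 0.
klDivergence <- function(p, q, base = 2) {
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos], base = base))
}

#' Jensen-Shannon divergence between two compositions (base 2)
#'
#' The symmetric, bounded divergence
#' `0.5 * sum(R_i * log2(R_i / M_i)) + 0.5 * sum(W_i * log2(W_i / M_i))` with
#' `M = (R + W) / 2`, using the convention that zero terms contribute 0 to
#' their own sum. Base 2 bounds the value by 1 (reached for disjoint
#' supports). `mode = "mixture-kl"` computes the identical quantity as the
#' mean KL divergence to the mixture, `0.5 KL(R||M) + 0.5 KL(W||M)`; it is
#' kept as an algebraically independent route for cross-checking.
#'
#' @param R,W simplex vectors of equal length.
#' @param mode `"two-term"` (default) or `"mixture-kl"`.
#' @return JSD in `[0, 1]`.
#' @examples
#' compositionJSD(c(1, 0), c(0, 1)) # 1 (maximal, base 2)
#' @export
compositionJSD <- function(R, W, mode = c("two-term", "mixture-kl")) {
  mode <- match.arg(mode)
  if (length(R) != length(W)) stop("R and W must have equal length")
  if (any(R < 0) || any(W < 0)) stop("compositions must be nonnegative")
  assertSimplex(R, "R")
  assertSimplex(W, "W")
  M <- 0.5 * (R + W)
  if (mode == "mixture-kl")
    return(0.5 * klDivergence(R, M) + 0.5 * klDivergence(W, M))
  termSum <- function(p) {
    pos <- p > 0 # zero terms contribute 0 to their own sum
    sum(p[pos] * log2(p[pos] / M[pos]))
  }
  0.5 * termSum(R) + 0.5 * termSum(W)
}

#' Mean Shannon entropy of a set of ROI compositions
#'
#' `(1/m) * sum_i H(r_i)` where `H` is the (nonnegative) Shannon entropy of
#' ROI i's composition. Higher values indicate more heterogeneous selected
#' regions.
#'
#' @param perROI list of composition vectors, or a matrix with one ROI per
#'   row.
#' @param base entropy logarithm base (default natural; 2 for bits).
#' @return nonnegative scalar.
#' @examples
#' meanROIEntropy(list(c(1, 0), c(0.5, 0.5)), base = 2) # 0.5 bits
#' @export
meanROIEntropy <- function(perROI, base = exp(1)) {
  if (is.matrix(perROI)) perROI <- asplit(perROI, 1L)
  if (length(perROI) == 0L) stop("empty ROI list")
  mean(vapply(perROI, shannonEntropy, numeric(1), base = base))
}

#' Pool the composition of a set of tiles
#'
#' Two pooling sources are supported, both over *valid* tiles only:
#' `"labels"` (canonical) counts the fraction of tiles per hard cluster
#' label — "percentage of tiles per cluster"; `"compositions"` averages the
#' per-tile composition vectors (exact pixel fractions when tiles carry
#' pixel-true compositions).
#'
#' @param grid a [TileGrid-class].
#' @param tiles integer tile indices (default: all tiles).
#' @param source `"labels"` or `"compositions"`.
#' @return length-K simplex vector.
#' @export
poolComposition <- function(grid, tiles = seq_len(nTiles(grid)),
                            source = c("labels", "compositions")) {
  source <- match.arg(source)
  tiles <- tiles[validTiles(grid)[tiles]]
  if (!length(tiles)) stop("no valid tiles to pool")
  K <- ncol(compositions(grid))
  if (source == "labels")
    tabulate(tileLabels(grid)[tiles], nbins = K) / length(tiles)
  else
    colMeans(compositions(grid)[tiles, , drop = FALSE])
}

#' Evaluate a selected ROI set against the whole-slide composition
#'
#' Pools all distinct valid tiles of the given windows into the combined
#' composition `R` (duplicate tiles from overlapping windows collapse), pools
#' all valid tiles of the grid into `W`, and reports the three selection
#' metrics: [compositionMSE()], base-2 [compositionJSD()], and
#' [meanROIEntropy()] over the individual window compositions.
#'
#' @param grid a [TileGrid-class].
#' @param windows data.frame of tile windows with columns `row0, col0,
#'   heightTiles, widthTiles` (0-based, half-open), e.g. the candidate rows
#'   of a [SelectionProblem-class] restricted to a support.
#' @param entropyBase base for the mean ROI entropy (default natural log).
#' @param source pooling source, see [poolComposition()].
#' @return a [SelectionReport-class].
#' @export
evaluateSelection <- function(grid, windows, entropyBase = exp(1),
                              source = c("labels", "compositions")) {
  source <- match.arg(source)
  stopifnot(is(grid, "TileGrid"))
  windows <- as.data.frame(windows)
  if (nrow(windows) == 0L) stop("empty window set")
  need <- c("row0", "col0", "heightTiles", "widthTiles")
  if (!all(need %in% names(windows)))
    stop("windows must have columns: ", paste(need, collapse = ", "))
  dims <- gridDim(grid)
  tileSets <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    if (w$row0 < 0 || w$col0 < 0 ||
        w$row0 + w$heightTiles > dims["rows"] ||
        w$col0 + w$widthTiles > dims["cols"])
      stop("window ", i, " lies outside the grid")
    windowTileIndices(w$row0, w$col0, w$heightTiles, w$widthTiles, dims["cols"])
  })
  perROI <- t(vapply(tileSets, function(ix) poolComposition(grid, ix, source),
                     numeric(ncol(compositions(grid)))))
  R <- poolComposition(grid, unique(unlist(tileSets)), source)
  W <- poolComposition(grid, source = source)
  new("SelectionReport",
    R = R, W = W, perROI = perROI,
    mse = compositionMSE(R, W),
    jsd = compositionJSD(R, W),
    meanEntropy = meanROIEntropy(perROI, base = entropyBase),
    entropyBase = entropyBase
  )
}
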