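# synthetic_data: tissue, embedding and mask generators with known truth.

#' Describe a synthetic tissue
#'
#' Builds the parameter object consumed by the generators. Defaults describe
#' the reference fixture used throughout the package: a 40 x 40 grid of
#' 256-px tiles (10,240 px square) with K = 7 spatially contiguous
#' tissue/cell-type clusters at unequal target proportions, blob length scale
#' 1,024 px (about four tiles, the scale of coherent histologic domains), and
#' noise-free tile compositions (`dirichletConc = Inf`).
#'
#' @param imageSizePx image size in px; scalar or length-2 (rows, cols).
#' @param tileSizePx pixels per tile side.
#' @param K number of clusters.
#' @param targetProportions length-K simplex vector of target global pixel
#'   proportions.
#' @param smoothnessPx Gaussian length scale of the label blobs, px.
#' @param dirichletConc Dirichlet concentration of per-tile composition noise
#'   (`Inf` = exact pixel-true compositions).
#' @param cellSizePx storage resolution of the label field (px per cell);
#'   must divide `tileSizePx`.
#' @param seed RNG seed.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(imageSizePx = 10240L, tileSizePx = 256L, K = 7L,
                          targetProportions = c(0.28, 0.20, 0.15, 0.12, 0.10, 0.08, 0.07),
                          smoothnessPx = 1024, dirichletConc = Inf,
                          cellSizePx = 32L, seed = 0L) {
  if (length(imageSizePx) == 1L) imageSizePx <- rep(imageSizePx, 2L)
  new("SyntheticSpec",
    imageSizePx = as.integer(imageSizePx), tileSizePx = as.integer(tileSizePx),
    K = as.integer(K), targetProportions = as.numeric(targetProportions),
    smoothnessPx = as.numeric(smoothnessPx),
    dirichletConc = as.numeric(dirichletConc),
    cellSizePx = as.integer(cellSizePx), seed = as.integer(seed)
  )
}

# Separable Gaussian blur of a matrix (truncated, row-normalized kernel).
gaussBlur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  kmat <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-0.5 * (d / sigma)^2)
    k[d > 4 * sigma] <- 0
    k / rowSums(k)
  }
  kmat(nrow(x)) %*% x %*% t(kmat(ncol(x)))
}

#' Generate a spatially contiguous label field
#'
#' Draws one white-noise field per cluster, smooths each with a Gaussian
#' kernel at the requested length scale, standardizes them, and labels every
#' cell by the argmax of `field_k + offset_k`. The offsets are tuned by a
#' damped fixed-point iteration (each update moves an offset monotonically
#' with its cluster's deficit) until the realized global proportions lie
#' within +/- 0.02 of `targetProportions`; if the tolerance cannot be reached
#' the achieved proportions are reported in the error. Output is
#' deterministic given the spec's seed.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a fully labeled [PixelLabelMap-class] at the spec's cell
#'   resolution.
#' @export
generateLabelField <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  nr <- spec@imageSizePx[1] %/% spec@cellSizePx
  nc <- spec@imageSizePx[2] %/% spec@cellSizePx
  if (nr < 1L || nc < 1L) stop("image smaller than one cell")
  K <- spec@K
  if (K == 1L)
    return(PixelLabelMap(matrix(1L, nr, nc), spec@cellSizePx))
  sigma <- spec@smoothnessPx / spec@cellSizePx
  fields <- withSeed(spec@seed, lapply(seq_len(K), function(k) {
    f <- gaussBlur(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
    (f - mean(f)) / stats::sd(f)
  }))
  target <- spec@targetProportions
  offsets <- rep(0, K)
  best <- NULL
  bestErr <- Inf
  labelsFor <- function(off) {
    lab <- matrix(1L, nr, nc)
    top <- fields[[1]] + off[1]
    for (k in 2:K) {
      fk <- fields[[k]] + off[k]
      sel <- fk > top
      lab[sel] <- k
      top[sel] <- fk[sel]
    }
    lab
  }
  # Coordinate descent with exact one-dimensional solves: holding the other
  # offsets fixed, cluster k's realized proportion is monotone in its offset
  # and the exact matching value is a quantile of the margin against the
  # best competitor, so each update is a closed-form monotone step.
  for (round in seq_len(40)) {
    for (k in seq_len(K)) {
      comp <- Reduce(pmax, lapply(setdiff(seq_len(K), k),
                                  function(l) fields[[l]] + offsets[l]))
      margin <- fields[[k]] - comp
      offsets[k] <- -stats::quantile(margin, probs = 1 - target[k], names = FALSE)
    }
    lab <- labelsFor(offsets)
    p <- tabulate(lab, nbins = K) / (nr * nc)
    err <- max(abs(p - target))
    if (err < bestErr) {
      bestErr <- err
      best <- lab
    }
    if (err <= 0.01) break
  }
  if (bestErr > 0.02) {
    p <- tabulate(best, nbins = K) / (nr * nc)
    stop("could not reach target proportions within 0.02 at this smoothness; ",
         "achieved: ", paste(sprintf("%.3f", p), collapse = ", "))
  }
  PixelLabelMap(best, spec@cellSizePx)
}

# Draw a Dirichlet vector with parameter alpha (zeros stay zero).
rdirichlet1 <- function(alpha) {
  pos <- alpha > 0
  if (!any(pos)) return(alpha) # empty tile: leave the zero row untouched
  g <- numeric(length(alpha))
  g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  if (sum(g) == 0) g[pos] <- alpha[pos] # numerical underflow fallback
  g / sum(g)
}

#' Generate a synthetic tile grid with ground truth
#'
#' Builds the label field, cuts it into tiles, and (optionally, when
#' `dirichletConc` is finite) resamples each tile's composition from a
#' Dirichlet distribution centered on the pixel-true composition. The pooled
#' pixel-true composition over the tiled area is stored in the grid metadata
#' as `truthProportions` (at `dirichletConc = Inf` it equals the pooled tile
#' composition exactly).
#'
#' @param spec a [SyntheticSpec-class].
#' @param field optional pre-generated [PixelLabelMap-class] (to reuse one
#'   field across calls); defaults to `generateLabelField(spec)`.
#' @return a [TileGrid-class]; `gridMeta(grid)$truthProportions` holds the
#'   ground-truth WSI composition, `gridMeta(grid)$spec` the spec.
#' @export
generateTileGrid <- function(spec, field = NULL) {
  stopifnot(is(spec, "SyntheticSpec"))
  if (is.null(field)) field <- generateLabelField(spec)
  grid <- buildGridFromLabelMap(field, spec@tileSizePx, K = spec@K)
  cpt <- spec@tileSizePx %/% field@cellSizePx
  nrC <- gridDim(grid)["rows"] * cpt
  ncC <- gridDim(grid)["cols"] * cpt
  tiled <- field@map[seq_len(nrC), seq_len(ncC), drop = FALSE]
  truth <- tabulate(tiled, nbins = spec@K) / length(tiled)
  if (is.finite(spec@dirichletConc)) {
    comp <- grid@compositions
    noisy <- withSeed(spec@seed + 1L, t(apply(comp, 1L, function(p)
      rdirichlet1(spec@dirichletConc * p))))
    grid@compositions <- noisy
    grid@labels <- max.col(noisy, ties.method = "first")
    validObject(grid)
  }
  grid@meta$truthProportions <- truth
  grid@meta$spec <- spec
  grid
}

#' Generate per-tile embeddings paired to compositions
#'
#' Emulates the latent features a cross-modal autoencoder would produce for
#' each tile: a fixed random linear map of the tile composition plus
#' isotropic Gaussian noise. With `noiseSd = 0` the embedding is an exact
#' linear image of the composition, so its first `K - 1` canonical
#' correlations against the compositions equal 1.
#'
#' @param grid a [TileGrid-class].
#' @param dim embedding dimension (default 16).
#' @param noiseSd Gaussian noise standard deviation (default 0).
#' @param seed RNG seed (default 0).
#' @return `grid` with its embedding slot set (`nTiles x dim`).
#' @export
generatePairedEmbeddings <- function(grid, dim = 16L, noiseSd = 0, seed = 0L) {
  stopifnot(is(grid, "TileGrid"))
  K <- ncol(compositions(grid))
  n <- nTiles(grid)
  emb <- withSeed(seed, {
    P <- matrix(stats::rnorm(K * dim), K, dim)
    compositions(grid) %*% P + if (noiseSd > 0)
      matrix(stats::rnorm(n * dim, sd = noiseSd), n, dim) else 0
  })
  tileEmbeddings(grid) <- emb
  grid
}

#' Generate a pair of binary masks with a target Dice coefficient
#'
#' The first mask is a thresholded smooth random field (about 40% foreground,
#' mimicking a nuclear mask); the second is the first with labels flipped
#' independently at a rate found by bisection so the realized Dice
#' coefficient lies within +/- 0.05 of `targetDice`. `targetDice = 1` returns
#' two identical masks.
#'
#' @param shape integer(2), mask dimensions in px.
#' @param targetDice target Dice coefficient in (0, 1].
#' @param seed RNG seed (default 0).
#' @param smoothnessPx length scale of the foreground blobs (default 8).
#' @return list with logical matrices `maskA`, `maskB` and the realized
#'   `dice`.
#' @export
generateMaskPair <- function(shape, targetDice, seed = 0L, smoothnessPx = 8) {
  stopifnot(length(shape) == 2L, targetDice > 0, targetDice <= 1)
  withSeed(seed, {
    f <- gaussBlur(matrix(stats::rnorm(prod(shape)), shape[1], shape[2]),
                   smoothnessPx)
    maskA <- f > stats::quantile(f, 0.6)
    if (targetDice >= 1) {
      return(list(maskA = maskA, maskB = maskA, dice = 1))
    }
    flips <- matrix(stats::runif(prod(shape)), shape[1], shape[2])
    flipAt <- function(p) xor(maskA, flips < p)
    lo <- 0
    hi <- 1
    for (i in seq_len(50)) {
      mid <- (lo + hi) / 2
      d <- diceCoefficient(maskA, flipAt(mid))
      if (d > targetDice) lo <- mid else hi <- mid
      if (abs(d - targetDice) <= 0.01) break
    }
    maskB <- flipAt((lo + hi) / 2)
    list(maskA = maskA, maskB = maskB, dice = diceCoefficient(maskA, maskB))
  })
}
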