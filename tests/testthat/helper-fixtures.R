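# Shared fixtures and independent reference implementations used as oracles.

# Small synthetic tissue: 6x6 tiles of 256 px, K = 7, ~1.5-tile blobs.
smallSpec <- function(seed, tiles = 6L, smoothnessPx = 384, K = 7L,
                      props = NULL) {
  if (is.null(props)) props <- c(0.28, 0.20, 0.15, 0.12, 0.10, 0.08, 0.07)[seq_len(K)]
  syntheticSpec(
    imageSizePx = tiles * 256L, tileSizePx = 256L, K = K,
    targetProportions = props / sum(props), smoothnessPx = smoothnessPx,
    cellSizePx = 32L, seed = seed
  )
}

# Selection problem from explicit columns (1x1-tile windows on one row, so
# distinct candidates never overlap).
problemFromColumns <- function(A, epsilon = 1e-3, lambda = 1,
                               b = rowMeans(A)) {
  M <- ncol(A)
  new("SelectionProblem",
    A = A, b = b, E = apply(A, 2, shannonEntropy), lambda = lambda,
    epsilon = epsilon,
    candidates = data.frame(row0 = 0L, col0 = seq_len(M) - 1L,
                            heightTiles = 1L, widthTiles = 1L),
    entropyBase = exp(1)
  )
}

# Random simplex columns.
randomColumns <- function(K, M, seed) {
  set.seed(seed)
  A <- matrix(stats::rexp(K * M), K, M)
  sweep(A, 2, colSums(A), "/")
}

# Reference NMI from the contingency table via the direct mutual-information
# sum (independent of the package's entropy-difference route).
refNMI <- function(u, v, average = "arithmetic") {
  n <- length(u)
  tab <- table(u, v)
  pij <- tab / n
  pi <- rowSums(pij)
  pj <- colSums(pij)
  mi <- 0
  for (i in seq_along(pi)) for (j in seq_along(pj)) {
    if (pij[i, j] > 0) mi <- mi + pij[i, j] * log(pij[i, j] / (pi[i] * pj[j]))
  }
  hu <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  hv <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  denom <- if (average == "arithmetic") (hu + hv) / 2 else sqrt(hu * hv)
  as.numeric(mi / denom)
}

# Reference JSD as the mean KL divergence to the mixture (base 2).
refJSD <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    ix <- a > 0
    sum(a[ix] * log2(a[ix] / b[ix]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

# Random simplex vector.
randomSimplex <- function(K) {
  x <- stats::rexp(K)
  x / sum(x)
}
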