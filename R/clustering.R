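# tile_clustering: k-means over tile features and cluster-agreement metrics.

#' Cluster tiles by k-means
#'
#' Lloyd's algorithm with k-means++-style seeding behaviour approximated by
#' multiple random restarts (`nstart`), run under a fixed seed so labels are
#' deterministic up to cluster-id permutation.
#'
#' @param vectors numeric matrix, one row per tile (composition or embedding).
#' @param k number of clusters (`1 <= k <= nrow(vectors)`).
#' @param seed RNG seed (default 0).
#' @param nstart random restarts (default 10).
#' @param iterMax Lloyd iterations per restart (default 100).
#' @return integer vector of cluster labels (1..k). If the data contain
#'   fewer than `k` distinct rows a warning is raised and tiles are assigned
#'   to the distinct rows (conceptually duplicated centroids).
#' @export
kmeansTiles <- function(vectors, k, seed = 0L, nstart = 10L, iterMax = 100L) {
  vectors <- as.matrix(vectors)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (nrow(vectors) < k) stop("need at least k tiles")
  if (k == 1L) return(rep(1L, nrow(vectors)))
  distinct <- unique(vectors)
  if (nrow(distinct) < k) {
    warning("fewer distinct vectors (", nrow(distinct), ") than k = ", k,
            "; duplicate centroids allowed")
    d2 <- outer(rowSums(vectors^2), rowSums(distinct^2), "+") -
      2 * vectors %*% t(distinct)
    return(max.col(-d2, ties.method = "first"))
  }
  fit <- withSeed(seed, suppressWarnings(
    stats::kmeans(vectors, centers = k, nstart = nstart,
                  iter.max = iterMax, algorithm = "Lloyd")
  ))
  as.integer(fit$cluster)
}

#' Choose k by the elbow of the within-cluster sum of squares
#'
#' Fits k-means over `kRange`, records the total within-cluster sum of
#' squares, and returns the knee: the k with the maximum second difference of
#' the curve. The full curve is returned so a caller can override the
#' automatic choice (e.g. pick a smaller k within the elbow). A
#' low-confidence flag is set when the strongest knee does not stand out
#' against the curvature of the rest of the curve (maximum second difference
#' below five times the median absolute second difference), as for data with
#' no pronounced elbow such as a single Gaussian.
#'
#' @param vectors numeric matrix, one row per tile.
#' @param kRange increasing integer vector of at least 3 candidate k.
#' @param seed RNG seed (default 0).
#' @return list with `k` (chosen), `kRange`, `withinSS` (curve),
#'   `secondDiff`, and `lowConfidence`.
#' @export
elbowSelectK <- function(vectors, kRange = 2:11, seed = 0L) {
  kRange <- as.integer(sort(kRange))
  if (length(kRange) < 3L) stop("kRange must contain at least 3 values")
  vectors <- as.matrix(vectors)
  wss <- vapply(kRange, function(k) {
    lab <- kmeansTiles(vectors, k, seed = seed)
    sum(vapply(split(seq_len(nrow(vectors)), lab), function(ix) {
      ctr <- colMeans(vectors[ix, , drop = FALSE])
      sum(sweep(vectors[ix, , drop = FALSE], 2, ctr)^2)
    }, numeric(1)))
  }, numeric(1))
  if (any(diff(wss) > 1e-8 * max(wss)))
    warning("within-SS curve is not monotone decreasing; consider more restarts")
  n <- length(wss)
  d2 <- wss[seq_len(n - 2L)] - 2 * wss[seq(2L, n - 1L)] + wss[seq(3L, n)]
  knee <- which.max(d2) + 1L
  drop <- wss[1] - wss[n]
  list(
    k = kRange[knee], kRange = kRange, withinSS = wss, secondDiff = d2,
    lowConfidence = drop <= 0 ||
      max(d2) < 5 * stats::median(abs(d2)) + 1e-12
  )
}

#' Cluster purity
#'
#' `(1/N) * sum over predicted clusters of the largest overlap with any
#' reference cluster`: the fraction of items lying in their predicted
#' cluster's majority reference class. Invariant to relabeling on either
#' side; splitting a predicted cluster can never decrease it.
#'
#' @param pred,truth equal-length label vectors without missing values.
#' @return purity in (0, 1].
#' @examples
#' clusterPurity(c(1, 1, 2, 2), c(1, 1, 1, 2)) # (2 + 1) / 4 = 0.75
#' @export
clusterPurity <- function(pred, truth) {
  if (length(pred) == 0L) stop("empty input")
  if (length(pred) != length(truth)) stop("pred and truth must have equal length")
  if (anyNA(pred) || anyNA(truth)) stop("missing labels are not allowed")
  tab <- table(pred, truth)
  sum(apply(tab, 1L, max)) / length(pred)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies (the geometric mean is available as an option). Computed with
#' natural logarithms internally; the normalization cancels the base.
#' Two single-class labelings are defined as NMI 1 (identical trivial
#' partitions); a single class on only one side gives 0.
#'
#' @param pred,truth equal-length label vectors.
#' @param average `"arithmetic"` (default) or `"geometric"` mean of the
#'   entropies in the denominator.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(pred, truth, average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  if (length(pred) != length(truth)) stop("pred and truth must have equal length")
  if (length(pred) == 0L) stop("empty input")
  n <- length(pred)
  hu <- shannonEntropy(table(pred) / n)
  hv <- shannonEntropy(table(truth) / n)
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  hj <- shannonEntropy(table(pred, truth) / n)
  mi <- max(0, hu + hv - hj)
  denom <- if (average == "arithmetic") (hu + hv) / 2 else sqrt(hu * hv)
  min(1, mi / denom)
}

#' Pair predicted clusters to reference clusters by Spearman correlation
#'
#' Computes the full Spearman correlation matrix between mean cluster
#' profiles (e.g. mean composition or mean marker vectors per cluster) and a
#' one-to-one assignment maximizing the total correlation (Hungarian
#' algorithm). Constant profiles yield undefined correlations, reported as
#' `NA` and treated as worst-case in the assignment.
#'
#' @param predProfiles numeric matrix, one row per predicted cluster.
#' @param truthProfiles numeric matrix, one row per reference cluster (same
#'   number of columns).
#' @param greedy if `TRUE`, use greedy best-first pairing instead of the
#'   optimal assignment (for comparison).
#' @return list with `correlation` (k_pred x k_truth matrix) and `assignment`
#'   (integer vector: truth index paired to each predicted cluster, `NA` for
#'   unpaired predicted clusters when k_pred > k_truth).
#' @export
pairClustersSpearman <- function(predProfiles, truthProfiles, greedy = FALSE) {
  predProfiles <- as.matrix(predProfiles)
  truthProfiles <- as.matrix(truthProfiles)
  if (ncol(predProfiles) != ncol(truthProfiles))
    stop("profile matrices must have the same number of columns")
  cm <- suppressWarnings(
    stats::cor(t(predProfiles), t(truthProfiles), method = "spearman")
  )
  score <- cm
  score[is.na(score)] <- -1.5 # below any admissible correlation
  kp <- nrow(score)
  kt <- ncol(score)
  assignment <- rep(NA_integer_, kp)
  if (greedy) {
    s <- score
    for (i in seq_len(min(kp, kt))) {
      ix <- arrayInd(which.max(s), dim(s))
      assignment[ix[1]] <- ix[2]
      s[ix[1], ] <- -Inf
      s[, ix[2]] <- -Inf
    }
  } else if (kp <= kt) {
    assignment[] <- as.integer(clue::solve_LSAP(score + 2, maximum = TRUE))
  } else {
    back <- as.integer(clue::solve_LSAP(t(score) + 2, maximum = TRUE))
    assignment[back] <- seq_len(kt)
  }
  list(correlation = cm, assignment = assignment)
}

#' Canonical correlation analysis between two tile-feature matrices
#'
#' Wraps [stats::cancor()]: per-component canonical correlations in
#' descending order plus the projected scores used for overlap scatter
#' plots. Rank-deficient inputs (e.g. compositions, which lose one dimension
#' on the simplex) are handled by `cancor`'s internal rank truncation; if
#' the decomposition fails outright a ridge-regularized fallback is used
#' with a warning.
#'
#' @param X,Y numeric matrices with equal row counts.
#' @param nComponents number of components to return (default 2).
#' @return list with `correlations` (length `nComponents`), `scoresX`,
#'   `scoresY` (n x nComponents projections).
#' @export
canonicalCorrelation <- function(X, Y, nComponents = 2L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  colnames(X) <- paste0(".x", seq_len(ncol(X)))
  colnames(Y) <- paste0(".y", seq_len(ncol(Y)))
  cc <- tryCatch(stats::cancor(X, Y), error = function(e) NULL)
  if (is.null(cc)) {
    warning("cancor failed on rank-deficient input; using ridge-regularized CCA")
    Xc <- scale(X, scale = FALSE)
    Yc <- scale(Y, scale = FALSE)
    Sxx <- crossprod(Xc) / nrow(X) + 1e-8 * diag(ncol(X))
    Syy <- crossprod(Yc) / nrow(Y) + 1e-8 * diag(ncol(Y))
    Sxy <- crossprod(Xc, Yc) / nrow(X)
    isq <- function(S) {
      e <- eigen(S, symmetric = TRUE)
      e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), nrow = ncol(S)) %*% t(e$vectors)
    }
    M <- isq(Sxx) %*% Sxy %*% isq(Syy)
    sv <- svd(M)
    xc <- isq(Sxx) %*% sv$u
    yc <- isq(Syy) %*% sv$v
    rownames(xc) <- colnames(X)
    rownames(yc) <- colnames(Y)
    cc <- list(cor = sv$d, xcoef = xc, ycoef = yc,
               xcenter = colMeans(X), ycenter = colMeans(Y))
  }
  nc <- min(nComponents, length(cc$cor))
  # cancor pivots and truncates rank-deficient inputs; its coefficient rows
  # are named after the retained columns.
  Xs <- sweep(X, 2L, cc$xcenter)[, rownames(cc$xcoef), drop = FALSE] %*%
    cc$xcoef[, seq_len(nc), drop = FALSE]
  Ys <- sweep(Y, 2L, cc$ycenter)[, rownames(cc$ycoef), drop = FALSE] %*%
    cc$ycoef[, seq_len(nc), drop = FALSE]
  list(
    correlations = cc$cor[seq_len(nc)],
    scoresX = Xs, scoresY = Ys
  )
}

#' Full agreement evaluation between a predicted and reference labeling
#'
#' Convenience wrapper combining [clusterPurity()], [nmi()],
#' [pairClustersSpearman()] on mean composition profiles and (optionally)
#' [canonicalCorrelation()].
#'
#' @param pred,truth label vectors.
#' @param features numeric matrix used to build mean cluster profiles
#'   (typically tile compositions); one row per item.
#' @param X,Y optional paired feature matrices for CCA.
#' @param nComponents CCA components (default 2).
#' @return a [ClusterEvaluation-class].
#' @export
evaluateClustering <- function(pred, truth, features, X = NULL, Y = NULL,
                               nComponents = 2L) {
  features <- as.matrix(features)
  profiles <- function(lab) {
    t(vapply(sort(unique(lab)), function(l)
      colMeans(features[lab == l, , drop = FALSE]), numeric(ncol(features))))
  }
  pr <- pairClustersSpearman(profiles(pred), profiles(truth))
  ccs <- if (!is.null(X) && !is.null(Y))
    canonicalCorrelation(X, Y, nComponents)$correlations else numeric(0)
  new("ClusterEvaluation",
    purity = clusterPurity(pred, truth), nmi = nmi(pred, truth),
    correlationMatrix = pr$correlation,
    assignment = as.integer(pr$assignment),
    canonicalCorrelations = as.numeric(ccs)
  )
}
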