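# roi_selection: candidate enumeration and the three selection strategies.

#' Enumerate candidate ROI windows and assemble the selection problem
#'
#' Slides a square `roiSideTiles` x `roiSideTiles` window over the tile grid
#' at the given stride (grid-aligned, half-open), keeping windows that
#' contain at least one valid tile. Column `j` of the matrix `A` is the
#' pooled composition of window `j`'s valid tiles; `E_j` is its Shannon
#' entropy; `b` is the pooled composition of all valid tiles of the slide.
#' At 256-px tiles the usual ROI pixel sizes 1000/1500/2000/2500 map to
#' window sides 4/6/8/10 tiles (`round(px / tileSizePx)`).
#'
#' @param grid a [TileGrid-class].
#' @param roiSideTiles window side in tiles (`<= min(gridDim)`).
#' @param strideTiles stride in tiles (default `roiSideTiles`, i.e.
#'   non-overlapping candidates that partition the grid).
#' @param source pooling source, see [poolComposition()].
#' @param entropyBase base of the candidate entropies (default natural log).
#' @param lambda,epsilon hyperparameters stored on the problem (defaults 1
#'   and 1e-3).
#' @return a [SelectionProblem-class].
#' @export
enumerateCandidates <- function(grid, roiSideTiles, strideTiles = roiSideTiles,
                                source = c("labels", "compositions"),
                                entropyBase = exp(1), lambda = 1,
                                epsilon = 1e-3) {
  source <- match.arg(source)
  stopifnot(is(grid, "TileGrid"))
  roiSideTiles <- as.integer(roiSideTiles)
  strideTiles <- as.integer(strideTiles)
  dims <- gridDim(grid)
  if (roiSideTiles > min(dims)) stop("roiSideTiles exceeds the grid")
  if (strideTiles < 1L) stop("strideTiles must be >= 1")
  r0 <- seq.int(0L, dims["rows"] - roiSideTiles, by = strideTiles)
  c0 <- seq.int(0L, dims["cols"] - roiSideTiles, by = strideTiles)
  cand <- expand.grid(row0 = r0, col0 = c0, KEEP.OUT.ATTRS = FALSE)
  cand <- cand[order(cand$row0, cand$col0), , drop = FALSE]
  cand$heightTiles <- roiSideTiles
  cand$widthTiles <- roiSideTiles
  K <- ncol(compositions(grid))
  keep <- logical(nrow(cand))
  cols <- matrix(0, K, nrow(cand))
  for (j in seq_len(nrow(cand))) {
    ix <- windowTileIndices(cand$row0[j], cand$col0[j], roiSideTiles,
                            roiSideTiles, dims["cols"])
    ix <- ix[validTiles(grid)[ix]]
    if (length(ix)) {
      keep[j] <- TRUE
      cols[, j] <- poolComposition(grid, ix, source)
    }
  }
  if (!any(keep)) stop("no candidate window contains a valid tile")
  A <- cols[, keep, drop = FALSE]
  cand <- cand[keep, , drop = FALSE]
  rownames(cand) <- NULL
  E <- apply(A, 2L, shannonEntropy, base = entropyBase)
  new("SelectionProblem",
    A = A, b = poolComposition(grid, source = source), E = E,
    lambda = lambda, epsilon = epsilon, candidates = cand,
    entropyBase = entropyBase
  )
}

# Box-constrained QP via quadprog: min 0.5 x'Dx - d'x, with optional
# sum(x) = 1 and elementwise bounds/slack constraints. Returns x or NULL
# when the constraints are inconsistent.
solveBoxQP <- function(D, d, A = NULL, b = NULL, epsilon = NULL,
                       simplex = FALSE, upper = rep(1, length(d))) {
  M <- length(d)
  Amat <- cbind(diag(M), -diag(M))
  bvec <- c(rep(0, M), -upper)
  meq <- 0L
  if (simplex) {
    Amat <- cbind(rep(1, M), Amat)
    bvec <- c(1, bvec)
    meq <- 1L
  }
  if (!is.null(A)) {
    Amat <- cbind(Amat, t(A), -t(A))
    bvec <- c(bvec, b - epsilon, -(b + epsilon))
  }
  sol <- tryCatch(
    quadprog::solve.QP(D, d, Amat, bvec, meq = meq),
    error = function(e) {
      if (grepl("constraints are inconsistent", conditionMessage(e))) NULL
      else stop(e)
    }
  )
  if (is.null(sol)) return(NULL)
  pmin(1, pmax(0, sol$solution))
}

# Equal-pooling composition of a candidate subset (mean of its columns).
equalPool <- function(A, S) rowMeans(A[, S, drop = FALSE])

# Does some weight vector 0 <= x <= 1 on the columns S satisfy
# |A_S x - b| <= eps elementwise?  Solved as a box-constrained minimization
# of the squared-hinge constraint violation (convex, so a single L-BFGS-B
# run finds the global minimum); independent of the QP solver.
weightedFeasible <- function(A, b, S, eps, tol = 1e-12) {
  As <- A[, S, drop = FALSE]
  m <- length(S)
  fn <- function(x) {
    r <- as.numeric(As %*% x - b)
    sum(pmax(0, abs(r) - eps)^2)
  }
  gr <- function(x) {
    r <- as.numeric(As %*% x - b)
    h <- sign(r) * pmax(0, abs(r) - eps)
    as.numeric(2 * crossprod(As, h))
  }
  opt <- stats::optim(rep(1 / m, m), fn, gr, method = "L-BFGS-B",
                      lower = 0, upper = 1, control = list(factr = 1e3))
  opt$value <= tol
}

# Maximum elementwise deviation of the equal-pooled subset from b.
poolResidual <- function(A, b, S) max(abs(equalPool(A, S) - b))

# Set objective of a support under equal pooling for the entropy strategy.
entropySetObjective <- function(A, b, E, S, lambda, s) {
  s^2 * sum((equalPool(A, S) - b)^2) - lambda * mean(E[S])
}

# Enumerate non-empty subsets of `ix` (used for support polishing).
allSubsets <- function(ix) {
  out <- list()
  for (m in seq_along(ix))
    out <- c(out, utils::combn(ix, m, simplify = FALSE))
  out
}

#' Sparse ROI selection by L1 minimization of candidate weights
#'
#' Solves `min sum(x)` subject to `|Ax - b| <= epsilon` elementwise and
#' `0 <= x <= 1`: the smallest (fractional) set of candidate ROIs whose
#' weighted composition reproduces the slide composition within the slack.
#' When the problem is infeasible at the requested slack, `epsilon` is
#' doubled (each retry reported via `message()`) up to `maxEpsilon`; beyond
#' that an error reports the closest achievable fit.
#'
#' The selected set is `{j : x_j > threshold}` (default cutoff 0.01). Since
#' the goal is the *minimum number* of ROIs and the LP optimum is one vertex
#' among possibly many, the support is then polished: adjacent optimal
#' vertices are explored by leave-one-out re-solves (each support member
#' forced to zero in turn), and the smallest subset of the pooled candidate
#' union that still admits weights satisfying the slack constraint is
#' returned (restricted solves, ascending size, lexicographic tie-break).
#' If no feasible subset improves on it the thresholded support is kept.
#'
#' @param problem a [SelectionProblem-class].
#' @param epsilon starting elementwise slack (default: the problem's).
#' @param threshold support cutoff on the weights (default 0.01).
#' @param maxEpsilon give up once the doubled slack exceeds this (default
#'   0.25).
#' @param polish logical, apply the support polish (default `TRUE`).
#' @return a [SelectionResult-class]; `supportObjective` is the number of
#'   selected ROIs, `epsilonUsed` the slack at which the solve succeeded.
#' @export
selectL1 <- function(problem, epsilon = problem@epsilon, threshold = 0.01,
                     maxEpsilon = 0.25, polish = TRUE) {
  stopifnot(is(problem, "SelectionProblem"))
  A <- problem@A
  b <- problem@b
  M <- ncol(A)
  # A plain ridge-regularized LP returns the analytic center of the optimal
  # face (weights spread uniformly and fall below the support threshold).
  # The graded cost perturbation makes the optimal vertex unique, so the
  # solver returns a basic solution with at most 2K nonzero weights; it
  # changes the objective by < 1e-5.
  D <- diag(1e-8, M)
  d <- -(1 + 1e-5 * seq_len(M) / M)
  eps <- epsilon
  x <- NULL
  repeat {
    x <- solveBoxQP(D, d, A = A, b = b, epsilon = eps)
    if (!is.null(x)) break
    eps <- eps * 2
    if (eps > maxEpsilon) {
      xf <- solveBoxQP(2 * crossprod(A) + diag(1e-8, M), 2 * crossprod(A, b))
      stop("L1 selection infeasible up to epsilon = ", maxEpsilon,
           "; closest achievable fit has max deviation ",
           format(max(abs(A %*% xf - b))))
    }
    message("L1 selection infeasible; doubling epsilon to ", eps)
  }
  support <- which(x > threshold)
  if (polish) {
    feasible <- function(S) {
      !is.null(solveBoxQP(diag(1e-8, length(S)), rep(-1, length(S)),
                          A = A[, S, drop = FALSE], b = b, epsilon = eps))
    }
    un <- support
    for (j in support) { # explore adjacent optimal vertices
      up <- rep(1, M)
      up[j] <- 0
      x2 <- solveBoxQP(D, d, A = A, b = b, epsilon = eps, upper = up)
      if (!is.null(x2)) un <- union(un, which(x2 > threshold))
    }
    un <- sort(un)
    limit <- if (length(support)) length(support) - 1L else length(un)
    for (m in seq_len(max(limit, 0L))) {
      if (choose(length(un), m) > 5e4) break
      hit <- NULL
      for (S in utils::combn(un, m, simplify = FALSE)) {
        if (feasible(S)) {
          hit <- S
          break
        }
      }
      if (!is.null(hit)) {
        support <- hit
        break
      }
    }
  }
  new("SelectionResult",
    x = x, support = as.integer(support), objective = sum(x),
    supportObjective = as.numeric(length(support)), status = "optimal",
    threshold = threshold, epsilonUsed = eps, method = "l1",
    lambda = NA_real_
  )
}

#' Entropy-regularized ROI selection
#'
#' Solves the quadratic program
#' `min ||Ax - b||^2 - lambda * E'x` subject to `0 <= x <= 1` and
#' `sum(x) = 1`, trading composition fidelity against the mean Shannon
#' entropy (heterogeneity) of the selected regions. With the default
#' `scale = "percent"` the fidelity term is computed on the percent-
#' composition scale (`||100 (Ax - b)||^2`), which is the scale on which the
#' default weight `lambda = 1` balances the two terms; `scale = "fraction"`
#' uses the raw simplex scale.
#'
#' The support is `{j : x_j > threshold}`; because the selected set is used
#' with unweighted pooling downstream, the reported support is then refined
#' against the equal-pooling set objective
#' `s^2 ||A u_S - b||^2 - lambda * mean(E_S)` by exhaustive subset
#' enumeration within the support (the fractional solve acts as a screening
#' step; refinement is skipped for supports above 14 candidates).
#'
#' @param problem a [SelectionProblem-class].
#' @param lambda entropy weight (default: the problem's, typically 1).
#' @param threshold support cutoff (default 0.01).
#' @param scale `"percent"` (default) or `"fraction"`.
#' @param entropySign `+1` (default) rewards heterogeneous ROIs; `-1` favors
#'   homogeneous ones.
#' @param refine logical, apply the discrete support refinement (default
#'   `TRUE`).
#' @return a [SelectionResult-class]; `objective` is the QP value at the
#'   fractional optimum, `supportObjective` the equal-pooling set objective
#'   of the reported support.
#' @export
selectEntropy <- function(problem, lambda = problem@lambda, threshold = 0.01,
                          scale = c("percent", "fraction"), entropySign = 1,
                          refine = TRUE) {
  scale <- match.arg(scale)
  stopifnot(is(problem, "SelectionProblem"), lambda >= 0)
  s <- if (scale == "percent") 100 else 1
  A <- problem@A
  b <- problem@b
  E <- entropySign * problem@E
  M <- ncol(A)
  D <- 2 * s^2 * crossprod(A) + diag(1e-6, M)
  d <- 2 * s^2 * as.numeric(crossprod(A, b)) + lambda * E
  x <- solveBoxQP(D, d, simplex = TRUE)
  if (is.null(x)) stop("entropy selection: solver reported inconsistent constraints")
  x <- x / sum(x)
  objective <- s^2 * sum((A %*% x - b)^2) - lambda * sum(E * x)
  support <- which(x > threshold)
  if (!length(support)) support <- which.max(x)
  g <- function(S) s^2 * sum((equalPool(A, S) - b)^2) - lambda * mean(E[S])
  if (refine && length(support) <= 14L) {
    # The QP acts as a screening step: the reported set is the best
    # equal-pooled subset of the thresholded support.
    subs <- allSubsets(support)
    vals <- vapply(subs, g, numeric(1))
    support <- subs[[which.min(vals)]]
  }
  support <- sort(support)
  new("SelectionResult",
    x = x, support = as.integer(support), objective = objective,
    supportObjective = g(support), status = "optimal",
    threshold = threshold, epsilonUsed = NA_real_, method = "entropy",
    lambda = lambda
  )
}

#' Random ROI-set baseline
#'
#' Draws `nDraws` random combinations of `k` pairwise non-overlapping
#' candidate windows (uniform without replacement, rejection sampling) and
#' evaluates each draw's combined composition against the slide: MSE, base-2
#' JSD and mean ROI entropy. This is the random-sampling baseline against
#' which the optimized selections are compared.
#'
#' @param problem a [SelectionProblem-class].
#' @param k ROIs per draw (typically the optimized support size).
#' @param nDraws number of random combinations (default 1000).
#' @param seed RNG seed (default 0).
#' @param maxAttempts rejection-sampling attempts per draw (default 1000).
#' @return list with `draws` (list of index vectors), `metrics` (data.frame
#'   with `mse`, `jsd`, `meanEntropy` per draw) and `summary` (quantiles
#'   0/5/25/50/75/95/100% per metric).
#' @export
randomSelection <- function(problem, k, nDraws = 1000L, seed = 0L,
                            maxAttempts = 1000L) {
  stopifnot(is(problem, "SelectionProblem"), k >= 1L)
  A <- problem@A
  b <- problem@b
  E <- problem@E
  M <- ncol(A)
  if (k > M) stop("k exceeds the number of candidates")
  cand <- problem@candidates
  wins <- lapply(seq_len(M), function(j) as.list(cand[j, ]))
  nonOverlapping <- function(S) {
    if (length(S) < 2L) return(TRUE)
    for (a in seq_along(S)[-1]) for (bb in seq_len(a - 1L))
      if (windowsOverlap(wins[[S[a]]], wins[[S[bb]]])) return(FALSE)
    TRUE
  }
  draws <- withSeed(seed, {
    lapply(seq_len(nDraws), function(i) {
      for (att in seq_len(maxAttempts)) {
        S <- sample.int(M, k)
        if (nonOverlapping(S)) return(sort(S))
      }
      stop("could not place ", k, " non-overlapping ROIs after ",
           maxAttempts, " attempts")
    })
  })
  metrics <- do.call(rbind, lapply(draws, function(S) {
    R <- equalPool(A, S)
    data.frame(mse = compositionMSE(R, b), jsd = compositionJSD(R, b),
               meanEntropy = mean(E[S]))
  }))
  qs <- c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1)
  list(
    draws = draws, metrics = metrics,
    summary = vapply(metrics, stats::quantile, numeric(length(qs)), probs = qs)
  )
}

#' Exhaustive-search oracle over candidate supports
#'
#' Enumerates every support of size up to `maxK` and returns the
#' objective-minimizing one. For `objective = "l1"` the value is the
#' smallest number of ROIs that admit weights `0 <= x <= 1` keeping
#' `A_S x` within `epsilon` of `b` elementwise (feasibility decided by an
#' independent penalized box-constrained minimization; ties break
#' lexicographically). For `objective = "entropy"` it is the minimum of the
#' equal-pooling set objective `s^2 ||A u_S - b||^2 - lambda * mean(E_S)`.
#' Intended as an independent cross-check on small problems; the
#' combinatorial budget is capped at 10^6 supports.
#'
#' @param problem a [SelectionProblem-class].
#' @param maxK largest support size to enumerate.
#' @param objective `"l1"` or `"entropy"`.
#' @param epsilon slack for the l1 feasibility test (default: the problem's).
#' @param lambda entropy weight (default: the problem's).
#' @param scale fidelity scale, as in [selectEntropy()].
#' @return list with `support` (integer vector; empty when no feasible l1
#'   support exists), `objective`, and `nEvaluated`.
#' @export
bruteForceSelect <- function(problem, maxK, objective = c("l1", "entropy"),
                             epsilon = problem@epsilon,
                             lambda = problem@lambda,
                             scale = c("percent", "fraction")) {
  objective <- match.arg(objective)
  scale <- match.arg(scale)
  stopifnot(is(problem, "SelectionProblem"))
  s <- if (scale == "percent") 100 else 1
  A <- problem@A
  b <- problem@b
  E <- problem@E
  M <- ncol(A)
  maxK <- min(maxK, M)
  total <- sum(choose(M, seq_len(maxK)))
  if (total > 1e6) stop("combinatorial budget exceeded: ", format(total), " supports")
  nEval <- 0L
  if (objective == "l1") {
    for (m in seq_len(maxK)) {
      subs <- utils::combn(M, m, simplify = FALSE)
      nEval <- nEval + length(subs)
      for (S in subs) {
        if (weightedFeasible(A, b, S, epsilon))
          return(list(support = S, objective = as.numeric(m), nEvaluated = nEval))
      }
    }
    return(list(support = integer(0), objective = Inf, nEvaluated = nEval))
  }
  bestVal <- Inf
  bestS <- integer(0)
  for (m in seq_len(maxK)) {
    subs <- utils::combn(M, m, simplify = FALSE)
    nEval <- nEval + length(subs)
    vals <- vapply(subs, function(S)
      entropySetObjective(A, b, E, S, lambda, s), numeric(1))
    if (min(vals) < bestVal) {
      bestVal <- min(vals)
      bestS <- subs[[which.min(vals)]]
    }
  }
  list(support = bestS, objective = bestVal, nEvaluated = nEval)
}

#' Greedy de-overlap of a selected support
#'
#' The convex selectors do not enforce pairwise non-overlap of the selected
#' windows (weights are fractional). This optional pass keeps supports
#' usable where physical non-overlap matters: candidates are visited in
#' decreasing weight order and dropped if they overlap an already kept one.
#'
#' @param problem a [SelectionProblem-class].
#' @param result a [SelectionResult-class].
#' @return the result with a (possibly reduced) non-overlapping support.
#' @export
greedyDeoverlap <- function(problem, result) {
  stopifnot(is(problem, "SelectionProblem"), is(result, "SelectionResult"))
  S <- result@support[order(result@x[result@support], decreasing = TRUE)]
  cand <- problem@candidates
  kept <- integer(0)
  for (j in S) {
    ok <- all(vapply(kept, function(l)
      !windowsOverlap(as.list(cand[j, ]), as.list(cand[l, ])), logical(1)))
    if (ok) kept <- c(kept, j)
  }
  result@support <- sort(kept)
  result
}
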