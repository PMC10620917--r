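#' @import methods
NULL

#' TileGrid: a tiled whole-slide image with per-tile compositions
#'
#' A `TileGrid` represents a whole-slide image (WSI) cut into non-overlapping
#' square tiles on a regular grid. Each tile carries a composition vector over
#' `K` tissue/cell-type clusters (a point on the simplex), a hard cluster
#' label (by default the argmax of the composition), an optional pathologist
#' annotation id, and a validity flag (background tiles are invalid and are
#' excluded from all downstream computations).
#'
#' Tiles are stored row-major: tile at 0-based grid position `(row, col)` is
#' row `row * nCols + col + 1` of the composition matrix.
#'
#' @slot nRows integer, number of tile rows.
#' @slot nCols integer, number of tile columns.
#' @slot tileSizePx integer, pixels per tile side.
#' @slot compositions numeric matrix, `nTiles x K`; each valid tile's row sums
#'   to 1.
#' @slot labels integer vector, cluster id (1..K) per tile.
#' @slot annotations integer vector, annotation id per tile, `NA` where no
#'   annotated pixel fell inside the tile.
#' @slot valid logical vector, `FALSE` for background/empty tiles.
#' @slot embeddings numeric matrix, `nTiles x D` per-tile feature embedding
#'   (0 columns when absent).
#' @slot meta list, free-form provenance (e.g. generator ground truth).
#'
#' @seealso [buildGridFromLabelMap()], [readTileTable()], [generateTileGrid()]
#' @export
setClass("TileGrid",
  representation(
    nRows = "integer", nCols = "integer", tileSizePx = "integer",
    compositions = "matrix", labels = "integer", annotations = "integer",
    valid = "logical", embeddings = "matrix", meta = "list"
  )
)

setValidity("TileGrid", function(object) {
  n <- object@nRows * object@nCols
  msg <- character()
  if (length(object@nRows) != 1L || object@nRows < 1L) msg <- c(msg, "nRows must be a positive scalar")
  if (length(object@nCols) != 1L || object@nCols < 1L) msg <- c(msg, "nCols must be a positive scalar")
  if (length(object@tileSizePx) != 1L || object@tileSizePx < 1L) msg <- c(msg, "tileSizePx must be >= 1")
  if (nrow(object@compositions) != n) msg <- c(msg, "compositions must have nRows*nCols rows")
  if (length(object@labels) != n) msg <- c(msg, "labels length must be nRows*nCols")
  if (length(object@valid) != n) msg <- c(msg, "valid length must be nRows*nCols")
  if (length(object@annotations) != n) msg <- c(msg, "annotations length must be nRows*nCols")
  comp <- object@compositions[object@valid, , drop = FALSE]
  if (nrow(comp)) {
    if (any(comp < -1e-9) || any(comp > 1 + 1e-9))
      msg <- c(msg, "composition entries must lie in [0, 1]")
    s <- rowSums(comp)
    if (any(abs(s - 1) > 1e-9))
      msg <- c(msg, "each valid tile's composition must sum to 1 (tolerance 1e-9)")
  }
  K <- ncol(object@compositions)
  lv <- object@labels[object@valid]
  if (length(lv) && (anyNA(lv) || any(lv < 1L | lv > K)))
    msg <- c(msg, sprintf("valid-tile labels must be in 1..%d", K))
  if (nrow(object@embeddings) > 0L && nrow(object@embeddings) != n)
    msg <- c(msg, "embeddings must have nRows*nCols rows (or none)")
  if (length(msg)) msg else TRUE
})

#' PixelLabelMap: a rasterized tissue/cell-type label image
#'
#' Integer label ids per pixel; 0 marks unlabeled pixels and ids 1..K the K
#' tissue/cell-type classes. To keep very large slides tractable the raster
#' may be stored at a coarser "cell" resolution: each stored entry stands for
#' a square block of `cellSizePx` x `cellSizePx` identically labeled pixels.
#' All pixel-counting operations account for this factor exactly, so a map
#' with `cellSizePx = 1` is a plain per-pixel image.
#'
#' @slot map integer matrix of label ids (0 = unlabeled).
#' @slot cellSizePx integer, pixels per stored cell side (default 1).
#'
#' @seealso [buildGridFromLabelMap()], [generateLabelField()]
#' @export
setClass("PixelLabelMap",
  representation(map = "matrix", cellSizePx = "integer")
)

setValidity("PixelLabelMap", function(object) {
  msg <- character()
  if (length(object@cellSizePx) != 1L || object@cellSizePx < 1L)
    msg <- c(msg, "cellSizePx must be >= 1")
  if (!length(object@map)) msg <- c(msg, "map must be non-empty")
  m <- object@map
  if (anyNA(m) || any(m < 0) || any(m != round(m)))
    msg <- c(msg, "map entries must be non-negative integers (0 = unlabeled)")
  if (length(msg)) msg else TRUE
})

#' SyntheticSpec: parameters of the synthetic tissue generator
#'
#' Describes a synthetic WSI with spatially contiguous regions of `K`
#' tissue/cell-type clusters, emulating the structure of a multiplexed-imaging
#' colorectal-cancer section: smooth blobs at a controllable length scale,
#' global cluster proportions close to a target, tiled into square tiles each
#' carrying a composition vector.
#'
#' @slot imageSizePx integer(2), raster height and width in pixels.
#' @slot tileSizePx integer, pixels per tile side.
#' @slot K integer, number of clusters (>= 1).
#' @slot targetProportions numeric(K) on the simplex; realized global pixel
#'   proportions are tuned to within +/- 0.02 of this.
#' @slot smoothnessPx numeric, Gaussian length scale of the label blobs in px.
#' @slot dirichletConc numeric, concentration of per-tile Dirichlet
#'   measurement noise around the pixel-true composition; `Inf` (default)
#'   means exact compositions.
#' @slot cellSizePx integer, resolution at which the label field is stored
#'   (see [PixelLabelMap-class]); must divide `tileSizePx`.
#' @slot seed integer, RNG seed; a fixed seed gives bit-identical output.
#'
#' @export
setClass("SyntheticSpec",
  representation(
    imageSizePx = "integer", tileSizePx = "integer", K = "integer",
    targetProportions = "numeric", smoothnessPx = "numeric",
    dirichletConc = "numeric", cellSizePx = "integer", seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (length(object@imageSizePx) != 2L || any(object@imageSizePx < 1L))
    msg <- c(msg, "imageSizePx must be two positive integers")
  if (object@K < 1L) msg <- c(msg, "K must be >= 1")
  if (length(object@targetProportions) != object@K)
    msg <- c(msg, "targetProportions must have length K")
  if (abs(sum(object@targetProportions) - 1) > 1e-8 || any(object@targetProportions < 0))
    msg <- c(msg, "targetProportions must lie on the simplex")
  if (object@tileSizePx %% object@cellSizePx != 0L)
    msg <- c(msg, "cellSizePx must divide tileSizePx")
  if (object@smoothnessPx <= 0) msg <- c(msg, "smoothnessPx must be > 0")
  if (length(msg)) msg else TRUE
})

#' SelectionProblem: candidate ROIs assembled for the convex selectors
#'
#' Holds the composition matrix `A` (one column per candidate ROI window, each
#' column a simplex vector over the K clusters), the slide-wide composition
#' `b`, and the per-candidate Shannon entropies `E`, together with the solver
#' hyperparameters: the entropy weight `lambda` and the elementwise
#' composition slack `epsilon`.
#'
#' @slot A numeric matrix, K x M; column j is candidate j's composition.
#' @slot b numeric(K), WSI composition (pooled over all valid tiles).
#' @slot E numeric(M), Shannon entropy of each candidate's composition.
#' @slot lambda numeric, entropy weight (default 1).
#' @slot epsilon numeric, elementwise slack for the L1 constraint (default 1e-3).
#' @slot candidates data.frame with columns `row0, col0, heightTiles,
#'   widthTiles` (0-based, half-open tile windows).
#' @slot entropyBase numeric, logarithm base used for `E`.
#'
#' @seealso [enumerateCandidates()], [selectL1()], [selectEntropy()]
#' @export
setClass("SelectionProblem",
  representation(
    A = "matrix", b = "numeric", E = "numeric", lambda = "numeric",
    epsilon = "numeric", candidates = "data.frame", entropyBase = "numeric"
  )
)

setValidity("SelectionProblem", function(object) {
  msg <- character()
  M <- ncol(object@A)
  if (length(object@b) != nrow(object@A)) msg <- c(msg, "length(b) must equal nrow(A)")
  if (length(object@E) != M) msg <- c(msg, "length(E) must equal ncol(A)")
  if (M > 0 && any(abs(colSums(object@A) - 1) > 1e-9))
    msg <- c(msg, "every column of A must sum to 1 (tolerance 1e-9)")
  if (abs(sum(object@b) - 1) > 1e-9) msg <- c(msg, "b must sum to 1")
  if (any(object@E < -1e-12)) msg <- c(msg, "entropies must be non-negative")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@epsilon < 0) msg <- c(msg, "epsilon must be >= 0")
  if (nrow(object@candidates) != M) msg <- c(msg, "candidates must have one row per column of A")
  if (length(msg)) msg else TRUE
})

#' SelectionResult: solver output for one ROI-selection run
#'
#' @slot x numeric(M), candidate weights in `[0, 1]`.
#' @slot support integer vector, selected candidate indices
#'   (`x > threshold`, possibly polished against the set objective).
#' @slot objective numeric, solver objective value at `x`.
#' @slot supportObjective numeric, set objective of the selected support under
#'   equal pooling (for `l1`: support size; for `entropy`: quadratic-minus-
#'   entropy value).
#' @slot status character, solver status.
#' @slot threshold numeric, support cutoff applied to `x`.
#' @slot epsilonUsed numeric, the slack at which the L1 solve succeeded
#'   (`NA` for the entropy solver).
#' @slot method character, `"l1"`, `"entropy"` or `"random"`.
#' @slot lambda numeric, entropy weight used (entropy method).
#'
#' @export
setClass("SelectionResult",
  representation(
    x = "numeric", support = "integer", objective = "numeric",
    supportObjective = "numeric", status = "character", threshold = "numeric",
    epsilonUsed = "numeric", method = "character", lambda = "numeric"
  )
)

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (length(object@x) && (any(object@x < -1e-8) || any(object@x > 1 + 1e-8)))
    msg <- c(msg, "weights x must lie in [0, 1]")
  if (length(object@support) && (any(object@support < 1L) || any(object@support > length(object@x))))
    msg <- c(msg, "support indices out of range")
  if (length(msg)) msg else TRUE
})

#' SelectionReport: evaluation of a selected ROI set against the WSI
#'
#' Compares the combined composition `R` of the selected ROIs (unweighted
#' pooling over all distinct tiles of all chosen windows) against the WSI
#' composition `W`, via mean squared error, base-2 Jensen-Shannon divergence,
#' and the mean Shannon entropy of the individual ROI compositions.
#'
#' @slot R numeric(K), combined composition of the selected ROIs.
#' @slot W numeric(K), WSI composition.
#' @slot perROI numeric matrix, m x K, composition of each selected ROI.
#' @slot mse numeric, mean squared error between `R` and `W`.
#' @slot jsd numeric in `[0, 1]`, base-2 Jensen-Shannon divergence.
#' @slot meanEntropy numeric, mean Shannon entropy over the m ROIs.
#' @slot entropyBase numeric, logarithm base of `meanEntropy`.
#'
#' @seealso [evaluateSelection()]
#' @export
setClass("SelectionReport",
  representation(
    R = "numeric", W = "numeric", perROI = "matrix", mse = "numeric",
    jsd = "numeric", meanEntropy = "numeric", entropyBase = "numeric"
  )
)

setValidity("SelectionReport", function(object) {
  msg <- character()
  if (length(object@R) != length(object@W)) msg <- c(msg, "R and W must have equal length")
  if (object@mse < 0) msg <- c(msg, "mse must be >= 0")
  if (!is.na(object@jsd) && (object@jsd < -1e-12 || object@jsd > 1 + 1e-12))
    msg <- c(msg, "base-2 JSD must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ClusterEvaluation: agreement between a predicted and a reference labeling
#'
#' @slot purity numeric in (0, 1], fraction of tiles falling in their
#'   predicted cluster's majority reference class.
#' @slot nmi numeric in `[0, 1]`, mutual information normalized by the mean
#'   entropy of the two labelings.
#' @slot correlationMatrix numeric matrix, k_pred x k_truth Spearman
#'   correlations between mean cluster profiles.
#' @slot assignment integer vector, optimal one-to-one pred -> truth pairing.
#' @slot canonicalCorrelations numeric vector, per-component canonical
#'   correlations (empty when CCA was not requested).
#'
#' @seealso [clusterPurity()], [nmi()], [pairClustersSpearman()],
#'   [canonicalCorrelation()]
#' @export
setClass("ClusterEvaluation",
  representation(
    purity = "numeric", nmi = "numeric", correlationMatrix = "matrix",
    assignment = "integer", canonicalCorrelations = "numeric"
  )
)

setValidity("ClusterEvaluation", function(object) {
  msg <- character()
  if (!is.na(object@purity) && (object@purity <= 0 || object@purity > 1 + 1e-12))
    msg <- c(msg, "purity must lie in (0, 1]")
  if (!is.na(object@nmi) && (object@nmi < -1e-12 || object@nmi > 1 + 1e-9))
    msg <- c(msg, "nmi must lie in [0, 1]")
  cm <- object@correlationMatrix
  if (length(cm) && any(abs(cm[!is.na(cm)]) > 1 + 1e-12))
    msg <- c(msg, "correlation entries must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})
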