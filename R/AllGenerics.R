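# Accessor generics and show methods.

#' @rdname TileGrid-class
#' @param x a `TileGrid`
#' @export
setGeneric("nTiles", function(x) standardGeneric("nTiles"))
#' @rdname TileGrid-class
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname TileGrid-class
#' @export
setGeneric("tileSize", function(x) standardGeneric("tileSize"))
#' @rdname TileGrid-class
#' @export
setGeneric("compositions", function(x) standardGeneric("compositions"))
#' @rdname TileGrid-class
#' @export
setGeneric("tileLabels", function(x) standardGeneric("tileLabels"))
#' @rdname TileGrid-class
#' @export
setGeneric("tileAnnotations", function(x) standardGeneric("tileAnnotations"))
#' @rdname TileGrid-class
#' @export
setGeneric("validTiles", function(x) standardGeneric("validTiles"))
#' @rdname TileGrid-class
#' @param value replacement value
#' @export
setGeneric("validTiles<-", function(x, value) standardGeneric("validTiles<-"))
#' @rdname TileGrid-class
#' @export
setGeneric("tileEmbeddings", function(x) standardGeneric("tileEmbeddings"))
#' @rdname TileGrid-class
#' @export
setGeneric("tileEmbeddings<-", function(x, value) standardGeneric("tileEmbeddings<-"))
#' @rdname TileGrid-class
#' @export
setGeneric("gridMeta", function(x) standardGeneric("gridMeta"))

#' @rdname TileGrid-class
#' @export
setMethod("nTiles", "TileGrid", function(x) x@nRows * x@nCols)
#' @rdname TileGrid-class
#' @export
setMethod("gridDim", "TileGrid", function(x) c(rows = x@nRows, cols = x@nCols))
#' @rdname TileGrid-class
#' @export
setMethod("tileSize", "TileGrid", function(x) x@tileSizePx)
#' @rdname TileGrid-class
#' @export
setMethod("compositions", "TileGrid", function(x) x@compositions)
#' @rdname TileGrid-class
#' @export
setMethod("tileLabels", "TileGrid", function(x) x@labels)
#' @rdname TileGrid-class
#' @export
setMethod("tileAnnotations", "TileGrid", function(x) x@annotations)
#' @rdname TileGrid-class
#' @export
setMethod("validTiles", "TileGrid", function(x) x@valid)
#' @rdname TileGrid-class
#' @export
setReplaceMethod("validTiles", "TileGrid", function(x, value) {
  stopifnot(is.logical(value), length(value) == nTiles(x))
  x@valid <- value
  validObject(x)
  x
})
#' @rdname TileGrid-class
#' @export
setMethod("tileEmbeddings", "TileGrid", function(x) x@embeddings)
#' @rdname TileGrid-class
#' @export
setReplaceMethod("tileEmbeddings", "TileGrid", function(x, value) {
  stopifnot(is.matrix(value), nrow(value) == nTiles(x))
  x@embeddings <- value
  validObject(x)
  x
})
#' @rdname TileGrid-class
#' @export
setMethod("gridMeta", "TileGrid", function(x) x@meta)

setMethod("show", "TileGrid", function(object) {
  cat(sprintf(
    "TileGrid: %d x %d tiles (%d px/tile), K = %d clusters\n",
    object@nRows, object@nCols, object@tileSizePx, ncol(object@compositions)
  ))
  cat(sprintf(
    "  valid tiles: %d / %d; annotated: %d; embedding dim: %d\n",
    sum(object@valid), nTiles(object), sum(!is.na(object@annotations)),
    ncol(object@embeddings)
  ))
})

setMethod("show", "PixelLabelMap", function(object) {
  d <- dim(object@map) * object@cellSizePx
  cat(sprintf(
    "PixelLabelMap: %d x %d px (stored at %d px/cell), %d label ids\n",
    d[1], d[2], object@cellSizePx, max(object@map)
  ))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d x %d px, tile %d px, K = %d, smoothness %.0f px, seed %d\n",
    object@imageSizePx[1], object@imageSizePx[2], object@tileSizePx,
    object@K, object@smoothnessPx, object@seed
  ))
})

setMethod("show", "SelectionProblem", function(object) {
  cat(sprintf(
    "SelectionProblem: %d clusters x %d candidate ROIs (lambda = %g, epsilon = %g)\n",
    nrow(object@A), ncol(object@A), object@lambda, object@epsilon
  ))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf(
    "SelectionResult [%s]: %d ROIs selected (threshold %g), objective %.6g, status %s\n",
    object@method, length(object@support), object@threshold,
    object@objective, object@status
  ))
})

setMethod("show", "SelectionReport", function(object) {
  cat(sprintf(
    "SelectionReport: %d ROIs | MSE %.4g | JSD(2) %.4g | mean entropy %.4g (base %g)\n",
    nrow(object@perROI), object@mse, object@jsd, object@meanEntropy,
    object@entropyBase
  ))
})

setMethod("show", "ClusterEvaluation", function(object) {
  cat(sprintf(
    "ClusterEvaluation: purity %.4f | NMI %.4f | %d paired clusters | %d canonical components\n",
    object@purity, object@nmi, length(object@assignment),
    length(object@canonicalCorrelations)
  ))
})

#' Selected support of a selection result
#' @param x a `SelectionResult`
#' @return integer vector of selected candidate indices
#' @export
setGeneric("selectedSupport", function(x) standardGeneric("selectedSupport"))
#' @rdname selectedSupport
#' @export
setMethod("selectedSupport", "SelectionResult", function(x) x@support)

#' Candidate weights of a selection result
#' @param x a `SelectionResult`
#' @return numeric vector of weights in `[0, 1]`
#' @export
setGeneric("selectionWeights", function(x) standardGeneric("selectionWeights"))
#' @rdname selectionWeights
#' @export
setMethod("selectionWeights", "SelectionResult", function(x) x@x)
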