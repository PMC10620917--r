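# tilegrid: data model and I/O for tiled whole-slide images.

#' Construct a TileGrid
#'
#' Low-level constructor; most users will build grids with
#' [buildGridFromLabelMap()], [readTileTable()] or [generateTileGrid()].
#'
#' @param nRows,nCols tile grid dimensions.
#' @param tileSizePx pixels per tile side.
#' @param compositions `nTiles x K` matrix of simplex rows (row-major tile
#'   order).
#' @param labels optional integer cluster ids (1..K); defaults to the argmax
#'   of each composition row (ties: lowest id).
#' @param annotations optional integer annotation ids (`NA` = none).
#' @param valid optional logical validity mask (default all valid).
#' @param embeddings optional `nTiles x D` feature matrix.
#' @param meta optional list of provenance metadata.
#' @return a [TileGrid-class] object.
#' @export
TileGrid <- function(nRows, nCols, tileSizePx, compositions, labels = NULL,
                     annotations = NULL, valid = NULL, embeddings = NULL,
                     meta = list()) {
  n <- as.integer(nRows) * as.integer(nCols)
  compositions <- as.matrix(compositions)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (is.null(labels)) {
    labels <- rep(NA_integer_, n)
    ok <- valid & rowSums(compositions) > 0
    labels[ok] <- max.col(compositions[ok, , drop = FALSE], ties.method = "first")
  }
  if (is.null(annotations)) annotations <- rep(NA_integer_, n)
  if (is.null(embeddings)) embeddings <- matrix(numeric(0), nrow = n, ncol = 0)
  new("TileGrid",
    nRows = as.integer(nRows), nCols = as.integer(nCols),
    tileSizePx = as.integer(tileSizePx), compositions = compositions,
    labels = as.integer(labels), annotations = as.integer(annotations),
    valid = as.logical(valid), embeddings = as.matrix(embeddings), meta = meta
  )
}

#' Construct a PixelLabelMap
#'
#' @param map integer matrix of label ids (0 = unlabeled).
#' @param cellSizePx pixels per stored cell side (default 1, i.e. per-pixel).
#' @return a [PixelLabelMap-class] object.
#' @export
PixelLabelMap <- function(map, cellSizePx = 1L) {
  storage.mode(map) <- "integer"
  new("PixelLabelMap", map = map, cellSizePx = as.integer(cellSizePx))
}

#' Cut a pixel label map into tiles and compute tile compositions
#'
#' The map is cut into non-overlapping `tileSizePx` x `tileSizePx` windows
#' (0-based, half-open); trailing partial tiles are dropped. Each tile's
#' composition entry `k` is the fraction of its *labeled* pixels carrying id
#' `k`; tiles with no labeled pixel are marked invalid. Pixel counts are
#' conserved: summing `composition * labeledPixels` over tiles reproduces the
#' map's per-id totals exactly.
#'
#' @param map a [PixelLabelMap-class].
#' @param tileSizePx pixels per tile side; must be a multiple of the map's
#'   cell size and no larger than the image.
#' @param K number of clusters (default: the largest id present).
#' @return a [TileGrid-class] with compositions, argmax labels and validity.
#' @examples
#' m <- PixelLabelMap(matrix(1L, 512, 512))
#' g <- buildGridFromLabelMap(m, 256)   # 2 x 2 grid, all tiles pure
#' @export
buildGridFromLabelMap <- function(map, tileSizePx, K = NULL) {
  stopifnot(is(map, "PixelLabelMap"))
  tileSizePx <- as.integer(tileSizePx)
  if (tileSizePx < 1L) stop("tileSizePx must be >= 1")
  if (tileSizePx %% map@cellSizePx != 0L)
    stop("tileSizePx must be a multiple of the map's cellSizePx (", map@cellSizePx, ")")
  cpt <- tileSizePx %/% map@cellSizePx # cells per tile side
  d <- dim(map@map)
  if (cpt > d[1] || cpt > d[2])
    stop("tile (", tileSizePx, " px) is larger than the image (",
         d[1] * map@cellSizePx, " x ", d[2] * map@cellSizePx, " px)")
  if (is.null(K)) K <- max(map@map)
  if (K < 1L) stop("label map contains no labeled pixels; K must be >= 1")
  nRows <- d[1] %/% cpt
  nCols <- d[2] %/% cpt
  sub <- map@map[seq_len(nRows * cpt), seq_len(nCols * cpt), drop = FALSE]
  cellRow <- (row(sub) - 1L) %/% cpt
  cellCol <- (col(sub) - 1L) %/% cpt
  idx <- cellRow * nCols + cellCol + 1L
  n <- nRows * nCols
  counts <- matrix(0, n, K)
  for (k in seq_len(K)) {
    sel <- sub == k
    if (any(sel)) counts[, k] <- tabulate(idx[sel], nbins = n)
  }
  labeled <- rowSums(counts)
  valid <- labeled > 0
  comp <- matrix(0, n, K)
  comp[valid, ] <- counts[valid, , drop = FALSE] / labeled[valid]
  TileGrid(nRows, nCols, tileSizePx, comp, valid = valid,
           meta = list(labeledPixelsPerTile = labeled * map@cellSizePx^2))
}

#' Assign per-tile ground-truth annotations from an annotation label map
#'
#' Each tile receives the annotation id with the largest pixel count inside
#' its window (ties broken deterministically toward the lowest id). Tiles
#' containing at least one annotated pixel are retained; tiles with none get
#' `NA` and are excluded from annotation-based analyses.
#'
#' @param map a [PixelLabelMap-class] of annotation ids (0 = unannotated); its
#'   pixel extent must cover the grid's tiled area.
#' @param grid a [TileGrid-class].
#' @return `grid` with its `annotations` slot filled.
#' @export
assignTileAnnotation <- function(map, grid) {
  stopifnot(is(map, "PixelLabelMap"), is(grid, "TileGrid"))
  if (grid@tileSizePx %% map@cellSizePx != 0L)
    stop("map cellSizePx must divide the grid's tileSizePx")
  cpt <- grid@tileSizePx %/% map@cellSizePx
  d <- dim(map@map)
  needR <- grid@nRows * cpt
  needC <- grid@nCols * cpt
  if (d[1] < needR || d[2] < needC)
    stop("annotation map extent (", d[1] * map@cellSizePx, " x ",
         d[2] * map@cellSizePx, " px) does not cover the grid (",
         needR * map@cellSizePx, " x ", needC * map@cellSizePx, " px)")
  sub <- map@map[seq_len(needR), seq_len(needC), drop = FALSE]
  K <- max(sub)
  n <- nTiles(grid)
  idx <- ((row(sub) - 1L) %/% cpt) * grid@nCols + ((col(sub) - 1L) %/% cpt) + 1L
  ann <- rep(NA_integer_, n)
  if (K >= 1L) {
    counts <- matrix(0, n, K)
    for (k in seq_len(K)) {
      sel <- sub == k
      if (any(sel)) counts[, k] <- tabulate(idx[sel], nbins = n)
    }
    has <- rowSums(counts) > 0
    ann[has] <- max.col(counts[has, , drop = FALSE], ties.method = "first")
  }
  grid@annotations <- ann
  validObject(grid)
  grid
}

#' Flag background tiles of an RGB slide image
#'
#' A tile is background when more than `maxFrac` (strict) of its pixels are
#' "white", i.e. all three 8-bit channels strictly exceed `whiteLevel`.
#' Defaults follow the usual H&E pre-processing rule: more than 70% of pixels
#' above (210, 210, 210).
#'
#' @param rgb numeric array `H x W x 3` of 8-bit intensities (0..255).
#'   Inputs that look like unit-range floats are rejected with instructions
#'   to rescale.
#' @param tileSizePx pixels per tile side; partial tiles are dropped.
#' @param whiteLevel 8-bit threshold a pixel must strictly exceed in every
#'   channel to count as white (default 210).
#' @param maxFrac background when the white-pixel fraction strictly exceeds
#'   this (default 0.70).
#' @return logical matrix (`tileRows x tileCols`), `TRUE` = background.
#' @export
filterBackgroundTiles <- function(rgb, tileSizePx, whiteLevel = 210,
                                  maxFrac = 0.70) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("rgb must be an H x W x 3 array")
  if (min(rgb) < 0 || max(rgb) > 255)
    stop("rgb must hold 8-bit values in 0..255; rescale before filtering")
  if (max(rgb) <= 1 && any(rgb %% 1 != 0))
    stop("rgb looks unit-ranged; rescale to 8-bit (0..255) before filtering")
  tileSizePx <- as.integer(tileSizePx)
  d <- dim(rgb)
  nR <- d[1] %/% tileSizePx
  nC <- d[2] %/% tileSizePx
  if (nR < 1L || nC < 1L) stop("tile is larger than the image")
  white <- (rgb[, , 1] > whiteLevel) & (rgb[, , 2] > whiteLevel) & (rgb[, , 3] > whiteLevel)
  white <- white[seq_len(nR * tileSizePx), seq_len(nC * tileSizePx), drop = FALSE]
  idx <- ((row(white) - 1L) %/% tileSizePx) * nC + ((col(white) - 1L) %/% tileSizePx) + 1L
  frac <- tabulate(idx[white], nbins = nR * nC) / tileSizePx^2
  matrix(frac > maxFrac, nR, nC, byrow = TRUE)
}

#' Rescale a grayscale image by intensity percentiles
#'
#' Linearly maps the `[loPct, hiPct]` intensity percentile range to `[0, 1]`,
#' clamping values outside it. The defaults (70th to 99.99th percentile)
#' follow the usual contrast normalization for immunofluorescence channels.
#'
#' @param image numeric matrix/array of intensities.
#' @param loPct,hiPct percentiles in `[0, 100]` with `loPct < hiPct`.
#' @return numeric object of the same shape with values in `[0, 1]`. A
#'   constant percentile range yields all zeros with a warning.
#' @export
rescaleIntensityPercentiles <- function(image, loPct = 70, hiPct = 99.99) {
  if (!(loPct >= 0 && loPct < hiPct && hiPct <= 100))
    stop("require 0 <= loPct < hiPct <= 100")
  q <- stats::quantile(image, probs = c(loPct, hiPct) / 100, names = FALSE, na.rm = TRUE)
  out <- image
  if (q[2] <= q[1]) {
    warning("constant percentile range; returning all zeros")
    out[] <- 0
    return(out)
  }
  out[] <- pmin(1, pmax(0, (image - q[1]) / (q[2] - q[1])))
  out
}

#' Read / write tile tables
#'
#' Tile tables are plain CSV files with one row per tile and columns `row`,
#' `col` (0-based grid position), `valid`, `label`, `annotation`,
#' `composition_1..composition_K` and optionally `embedding_1..embedding_D`.
#' Writing then reading a grid reproduces it losslessly at the numeric
#' precision of the text format (15 significant digits).
#'
#' Tables carrying only `label` (no composition columns) are accepted: each
#' tile then gets the one-hot composition of its label. Valid rows whose
#' composition does not sum to 1 within `tol` raise an error listing the
#' offending rows.
#'
#' @param path file path of the CSV.
#' @param tileSizePx pixels per tile side recorded in the grid (the table
#'   itself stores tile coordinates only); default 256.
#' @param tol tolerance on composition row sums (default 1e-6).
#' @return `readTileTable` returns a [TileGrid-class]; `writeTileTable`
#'   invisibly returns `path`.
#' @export
readTileTable <- function(path, tileSizePx = 256L, tol = 1e-6) {
  df <- utils::read.csv(path, comment.char = "#")
  req <- c("row", "col")
  if (!all(req %in% names(df)))
    stop("tile table must contain columns: ", paste(req, collapse = ", "))
  compCols <- grep("^composition_[0-9]+$", names(df), value = TRUE)
  if (!length(compCols) && !("label" %in% names(df)))
    stop("tile table needs composition_* columns or a label column")
  nRows <- max(df$row) + 1L
  nCols <- max(df$col) + 1L
  n <- nRows * nCols
  if (nrow(df) != n || anyDuplicated(df[c("row", "col")]))
    stop("tile table must contain exactly one row per (row, col) grid cell")
  ord <- order(df$row, df$col)
  df <- df[ord, , drop = FALSE]
  valid <- if ("valid" %in% names(df)) as.logical(df$valid) else rep(TRUE, n)
  if (length(compCols)) {
    kIds <- as.integer(sub("composition_", "", compCols))
    comp <- as.matrix(df[compCols[order(kIds)]])
    dimnames(comp) <- NULL
    sums <- rowSums(comp)
    bad <- which(valid & abs(sums - 1) > tol)
    if (length(bad))
      stop("composition rows do not sum to 1 (tolerance ", tol, ") at table rows: ",
           paste(utils::head(bad, 10), collapse = ", "),
           if (length(bad) > 10) sprintf(" ... (%d total)", length(bad)) else "")
  } else {
    K <- max(df$label, na.rm = TRUE)
    comp <- matrix(0, n, K)
    ok <- valid & !is.na(df$label)
    comp[cbind(which(ok), df$label[ok])] <- 1
  }
  labels <- if ("label" %in% names(df)) as.integer(df$label) else NULL
  ann <- if ("annotation" %in% names(df)) as.integer(df$annotation) else NULL
  embCols <- grep("^embedding_[0-9]+$", names(df), value = TRUE)
  emb <- NULL
  if (length(embCols)) {
    dIds <- as.integer(sub("embedding_", "", embCols))
    emb <- as.matrix(df[embCols[order(dIds)]])
    dimnames(emb) <- NULL
  }
  TileGrid(nRows, nCols, tileSizePx, comp, labels = labels,
           annotations = ann, valid = valid, embeddings = emb)
}

#' @rdname readTileTable
#' @param grid a [TileGrid-class] to serialize.
#' @export
writeTileTable <- function(grid, path) {
  stopifnot(is(grid, "TileGrid"))
  n <- nTiles(grid)
  df <- data.frame(
    row = rep(seq_len(grid@nRows) - 1L, each = grid@nCols),
    col = rep(seq_len(grid@nCols) - 1L, times = grid@nRows),
    valid = grid@valid,
    label = grid@labels,
    annotation = grid@annotations
  )
  comp <- grid@compositions
  colnames(comp) <- paste0("composition_", seq_len(ncol(comp)))
  df <- cbind(df, comp)
  if (ncol(grid@embeddings)) {
    emb <- grid@embeddings
    colnames(emb) <- paste0("embedding_", seq_len(ncol(emb)))
    df <- cbind(df, emb)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write label maps as single-channel rasters
#'
#' Label maps are stored as 16-bit grayscale TIFF or PNG images whose integer
#' pixel values are the label ids (0 = unlabeled). Cell-resolution maps
#' record their `cellSizePx` in the filename-independent sidecar argument on
#' read.
#'
#' @param path image path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#' @param cellSizePx pixels per stored cell when reading (default 1).
#' @return `readLabelMap` returns a [PixelLabelMap-class]; `writeLabelMap`
#'   invisibly returns `path`.
#' @export
readLabelMap <- function(path, cellSizePx = 1L) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported raster format: .", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1]
  scale <- if (ext == "png") 255 else 65535
  PixelLabelMap(matrix(as.integer(round(img * scale)), nrow(img), ncol(img)),
                cellSizePx = cellSizePx)
}

#' @rdname readLabelMap
#' @param map a [PixelLabelMap-class] to serialize.
#' @export
writeLabelMap <- function(map, path) {
  stopifnot(is(map, "PixelLabelMap"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = {
      if (max(map@map) > 65535) stop("label ids exceed 16-bit storage")
      tiff::writeTIFF(map@map / 65535, path, bits.per.sample = 16)
    },
    png = {
      if (max(map@map) > 255) stop("label ids exceed 8-bit PNG storage")
      png::writePNG(map@map / 255, path)
    },
    stop("unsupported raster format: .", ext)
  )
  invisible(path)
}
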