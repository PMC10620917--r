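# stain_eval: virtual-stain quality metrics on paired adjacent sections.

#' Dice coefficient between two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`. Two empty masks agree trivially and return 1.
#'
#' @param maskA,maskB logical (or 0/1) matrices of the same shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
diceCoefficient <- function(maskA, maskB) {
  if (!all(dim(maskA) == dim(maskB))) stop("masks must have the same shape")
  a <- as.logical(maskA)
  b <- as.logical(maskB)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Valid-mode moving average over a w x w window via summed-area tables.
movingMean <- function(x, w) {
  sat <- apply(apply(x, 2L, cumsum), 1L, cumsum) # transposed SAT
  sat <- t(sat)
  pad <- rbind(0, cbind(0, sat))
  n <- nrow(x) - w + 1L
  m <- ncol(x) - w + 1L
  i <- seq_len(n)
  j <- seq_len(m)
  (pad[i + w, j + w, drop = FALSE] - pad[i, j + w, drop = FALSE] -
    pad[i + w, j, drop = FALSE] + pad[i, j, drop = FALSE]) / (w * w)
}

#' Mean structural similarity with a square sliding window
#'
#' Standard SSIM (uniform window, sample-covariance normalization, constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`) averaged over all fully interior
#' window positions — the same contract as the common reference
#' implementations. The default is an 11-pixel window on unit-range images.
#'
#' @param x,y numeric matrices of the same shape with intensities in
#'   `[0, dataRange]`.
#' @param windowPx odd window side (default 11).
#' @param dataRange intensity range `L` (default 1).
#' @return mean SSIM in `[-1, 1]` (1 iff `x == y`).
#' @export
windowedSSIM <- function(x, y, windowPx = 11L, dataRange = 1) {
  if (!all(dim(x) == dim(y))) stop("images must have the same shape")
  windowPx <- as.integer(windowPx)
  if (windowPx %% 2L == 0L) stop("windowPx must be odd")
  if (nrow(x) < windowPx || ncol(x) < windowPx)
    stop("image smaller than the window")
  w <- windowPx
  N <- w * w
  covNorm <- N / (N - 1) # sample covariance
  ux <- movingMean(x, w)
  uy <- movingMean(y, w)
  uxx <- movingMean(x * x, w)
  uyy <- movingMean(y * y, w)
  uxy <- movingMean(x * y, w)
  vx <- covNorm * (uxx - ux^2)
  vy <- covNorm * (uyy - uy^2)
  vxy <- covNorm * (uxy - ux * uy)
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(S)
}

#' Dice-compensated SSIM
#'
#' Divides the SSIM of a virtual stain (against the real stain from the
#' adjacent section) by the Dice coefficient of the nuclear masks of the two
#' sections, compensating for genuine section-to-section content drift.
#' Values above 1 are possible and reported as-is (with an attribute flag).
#'
#' @param ssimValue SSIM of virtual vs real stain.
#' @param diceValue nuclear-mask Dice coefficient of the adjacent sections.
#' @return compensated SSIM (`NA` with a warning when `diceValue` is 0);
#'   attribute `exceedsOne` flags values above 1.
#' @export
compensatedSSIM <- function(ssimValue, diceValue) {
  if (diceValue == 0) {
    warning("Dice coefficient is 0; compensated SSIM undefined")
    return(NA_real_)
  }
  out <- ssimValue / diceValue
  attr(out, "exceedsOne") <- out > 1
  out
}

#' Fraction of marker-positive cells
#'
#' Fraction of cells whose mean marker intensity strictly exceeds the gating
#' threshold.
#'
#' @param cellTable data.frame of per-cell mean intensities.
#' @param marker column name of the marker.
#' @param gateThreshold positivity gate on the marker's intensity scale.
#' @return fraction in `[0, 1]`.
#' @export
positiveCellRatio <- function(cellTable, marker, gateThreshold) {
  if (!nrow(cellTable)) stop("empty cell table")
  if (!marker %in% names(cellTable)) stop("no column '", marker, "' in cell table")
  mean(cellTable[[marker]] > gateThreshold)
}

#' Correlate positive-cell ratios between real and virtual stains
#'
#' Pearson correlation and two-sided p-value between per-ROI positive-cell
#' ratios derived from real and virtual whole-slide stains.
#'
#' @param realRatios,virtualRatios equal-length numeric vectors (>= 3 ROIs).
#' @return list with `r`, `pValue`, `n` (`r`/`pValue` `NA` with a warning
#'   when either side has zero variance).
#' @export
correlateRatios <- function(realRatios, virtualRatios) {
  if (length(realRatios) != length(virtualRatios))
    stop("ratio vectors must have equal length")
  if (length(realRatios) < 3L) stop("need at least 3 ROIs")
  if (stats::sd(realRatios) == 0 || stats::sd(virtualRatios) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, pValue = NA_real_, n = length(realRatios)))
  }
  ct <- stats::cor.test(realRatios, virtualRatios, method = "pearson")
  list(r = unname(ct$estimate), pValue = ct$p.value, n = length(realRatios))
}

#' Evaluate a set of stain pairs
#'
#' Per-ROI report of Dice, windowed SSIM and Dice-compensated SSIM for
#' paired real/virtual stain images with the nuclear masks of the adjacent
#' sections, plus the median compensated value across ROIs.
#'
#' @param pairs list of lists with elements `real`, `virtual` (unit-range
#'   matrices), `maskA`, `maskB` (binary matrices) and optionally `roiId`.
#' @param windowPx SSIM window (default 11).
#' @return list with `perROI` data.frame (`roiId`, `dice`, `ssim`,
#'   `compensatedSSIM`, `exceedsOne`) and `medianCompensated`.
#' @export
evaluateStainPairs <- function(pairs, windowPx = 11L) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    d <- diceCoefficient(p$maskA, p$maskB)
    s <- windowedSSIM(p$real, p$virtual, windowPx = windowPx)
    cs <- compensatedSSIM(s, d)
    data.frame(
      roiId = if (is.null(p$roiId)) i else p$roiId,
      dice = d, ssim = s, compensatedSSIM = as.numeric(cs),
      exceedsOne = isTRUE(attr(cs, "exceedsOne"))
    )
  })
  perROI <- do.call(rbind, rows)
  list(perROI = perROI,
       medianCompensated = stats::median(perROI$compensatedSSIM, na.rm = TRUE))
}
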