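test_that("tiling a homogeneous label map gives pure compositions", {
  m <- PixelLabelMap(matrix(1L, 512, 512))
  g <- buildGridFromLabelMap(m, 256)
  expect_equal(unname(gridDim(g)), c(2L, 2L))
  expect_true(all(validTiles(g)))
  expect_equal(compositions(g), matrix(1, 4, 1))
  expect_equal(tileLabels(g), rep(1L, 4))
})

test_that("a half-and-half map yields a balanced single-tile composition", {
  m <- matrix(1L, 256, 256)
  m[, 129:256] <- 2L
  g <- buildGridFromLabelMap(PixelLabelMap(m), 256)
  expect_equal(compositions(g), matrix(c(0.5, 0.5), 1, 2))
})

test_that("tile compositions match brute-force pixel counting", {
  # 25% / 25% / 50% blocks plus a randomized map checked against table()
  m <- matrix(3L, 256, 256)
  m[1:128, 1:128] <- 1L
  m[1:128, 129:256] <- 2L
  g <- buildGridFromLabelMap(PixelLabelMap(m), 256)
  expect_equal(compositions(g)[1, ], c(0.25, 0.25, 0.5))

  set.seed(11)
  m2 <- matrix(sample(0:4, 96 * 96, replace = TRUE), 96, 96)
  g2 <- buildGridFromLabelMap(PixelLabelMap(m2), 32)
  for (tr in 0:2) for (tc in 0:2) {
    px <- m2[tr * 32 + 1:32, tc * 32 + 1:32]
    cnt <- table(factor(px[px > 0], levels = 1:4))
    expect_equal(compositions(g2)[tr * 3 + tc + 1, ],
                 unname(as.numeric(cnt) / sum(cnt)))
  }
})

test_that("pixel counts are conserved and partial tiles are dropped", {
  set.seed(7)
  m <- matrix(sample(0:3, 100 * 70, replace = TRUE), 100, 70)
  g <- buildGridFromLabelMap(PixelLabelMap(m), 32)
  expect_equal(unname(gridDim(g)), c(3L, 2L))
  kept <- m[1:96, 1:64]
  lp <- gridMeta(g)$labeledPixelsPerTile
  perId <- colSums(compositions(g) * lp)
  expect_equal(perId, as.numeric(table(factor(kept[kept > 0], levels = 1:3))))
  expect_error(buildGridFromLabelMap(PixelLabelMap(m), 128), "larger than the image")
})

test_that("tiles with no labeled pixels are invalid", {
  m <- matrix(0L, 64, 64)
  m[1:32, 1:32] <- 2L
  g <- buildGridFromLabelMap(PixelLabelMap(m), 32)
  expect_equal(validTiles(g), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("tile annotation takes the pixel-wise majority with a lowest-id tie rule", {
  base <- buildGridFromLabelMap(PixelLabelMap(matrix(1L, 20, 10)), 10)
  ann <- matrix(0L, 20, 10)
  ann[1:10, ] <- rep(c(2L, 3L), times = c(6, 4) * 10) # 60% id 2 / 40% id 3
  ann[11:15, ] <- 4L                                  # tie 50/50 between 4 and 1
  ann[16:20, ] <- 1L
  g <- assignTileAnnotation(PixelLabelMap(ann), base)
  expect_equal(tileAnnotations(g)[1], 2L)
  expect_equal(tileAnnotations(g)[2], 1L) # lowest id wins the tie

  ann0 <- matrix(0L, 20, 10)
  ann0[1, 1] <- 5L # a single annotated pixel retains the tile
  g0 <- assignTileAnnotation(PixelLabelMap(ann0), base)
  expect_equal(tileAnnotations(g0), c(5L, NA_integer_))

  expect_error(assignTileAnnotation(PixelLabelMap(matrix(1L, 5, 5)), base),
               "does not cover")
})

test_that("background filtering uses the strict 70% white-pixel rule", {
  mk <- function(fracWhite) {
    n <- 10
    nWhite <- round(fracWhite * n * n)
    ch <- matrix(0, n, n)
    ch[seq_len(nWhite)] <- 255
    array(rep(ch, 3), dim = c(n, n, 3))
  }
  expect_true(filterBackgroundTiles(mk(1), 10)[1, 1])
  expect_false(filterBackgroundTiles(mk(0), 10)[1, 1])
  expect_false(filterBackgroundTiles(mk(0.70), 10)[1, 1]) # exactly 70%: kept
  expect_true(filterBackgroundTiles(mk(0.71), 10)[1, 1])
  expect_error(filterBackgroundTiles(array(0.5, dim = c(10, 10, 3)), 10),
               "rescale")
})

test_that("background filtering is idempotent under tile reordering", {
  set.seed(3)
  img <- array(sample(0:255, 40 * 20 * 3, replace = TRUE), dim = c(40, 20, 3))
  img[1:20, 1:20, ] <- 255
  m1 <- filterBackgroundTiles(img, 20)
  swapped <- img[c(21:40, 1:20), , , drop = FALSE]
  m2 <- filterBackgroundTiles(swapped, 20)
  expect_equal(m1[c(2, 1), , drop = FALSE], m2)
  expect_equal(filterBackgroundTiles(img, 20), m1)
})

test_that("percentile rescaling maps the range to [0, 1] and flags constants", {
  ramp <- matrix(seq(0, 255, length.out = 256), 16, 16)
  out <- rescaleIntensityPercentiles(ramp, 0, 100)
  expect_equal(out, (ramp - min(ramp)) / diff(range(ramp)))
  img <- matrix(runif(1e4), 100, 100)
  out2 <- rescaleIntensityPercentiles(img) # defaults 70 / 99.99
  q <- quantile(img, c(0.70, 0.9999), names = FALSE)
  expect_equal(min(out2), 0)
  expect_equal(max(out2), 1)
  expect_equal(out2[img <= q[1]], rep(0, sum(img <= q[1])))
  expect_warning(res <- rescaleIntensityPercentiles(matrix(5, 4, 4)), "constant")
  expect_true(all(res == 0))
  expect_error(rescaleIntensityPercentiles(ramp, 80, 20))
})

test_that("tile tables round-trip losslessly", {
  g <- generateTileGrid(smallSpec(1))
  g <- generatePairedEmbeddings(g, dim = 3, noiseSd = 0.2, seed = 2)
  g@annotations <- sample(c(NA, 1:3), nTiles(g), replace = TRUE)
  path <- tempfile(fileext = ".csv")
  writeTileTable(g, path)
  g2 <- readTileTable(path, tileSizePx = tileSize(g))
  expect_equal(compositions(g2), compositions(g), tolerance = 1e-12)
  expect_identical(tileLabels(g2), tileLabels(g))
  expect_identical(tileAnnotations(g2), tileAnnotations(g))
  expect_identical(validTiles(g2), validTiles(g))
  expect_equal(tileEmbeddings(g2), tileEmbeddings(g), tolerance = 1e-12)
})

test_that("tile tables validate composition sums and accept label-only input", {
  df <- data.frame(row = c(0, 0), col = c(0, 1),
                   composition_1 = c(0.5, 0.3), composition_2 = c(0.5, 0.5))
  bad <- tempfile(fileext = ".csv")
  write.csv(df, bad, row.names = FALSE)
  expect_error(readTileTable(bad), "sum to 1")

  df2 <- data.frame(row = c(0, 0), col = c(0, 1), label = c(2L, 1L))
  lab <- tempfile(fileext = ".csv")
  write.csv(df2, lab, row.names = FALSE)
  g <- readTileTable(lab)
  expect_equal(compositions(g), matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
})

test_that("label maps round-trip through TIFF and PNG", {
  set.seed(5)
  m <- PixelLabelMap(matrix(sample(0:6, 64 * 48, replace = TRUE), 64, 48),
                     cellSizePx = 4L)
  for (ext in c(".tif", ".png")) {
    p <- tempfile(fileext = ext)
    writeLabelMap(m, p)
    m2 <- readLabelMap(p, cellSizePx = 4L)
    expect_identical(m2@map, m@map)
    expect_identical(m2@cellSizePx, 4L)
  }
})
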