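test_that("Dice coefficient matches its closed form and invariances", {
  a <- matrix(FALSE, 8, 8)
  a[2:4, 2:4] <- TRUE
  expect_equal(diceCoefficient(a, a), 1)
  b <- matrix(FALSE, 8, 8)
  b[6:8, 6:8] <- TRUE
  expect_equal(diceCoefficient(a, b), 0)
  # |A| = |B| = 2, |A & B| = 1
  a2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  b2 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(diceCoefficient(a2, b2), 0.5)
  expect_equal(diceCoefficient(b2, a2), 0.5) # symmetry
  expect_equal(diceCoefficient(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), 1)
  # joint translation leaves Dice unchanged
  shift <- function(m) rbind(m[-1, ], FALSE)
  expect_equal(diceCoefficient(shift(a), shift(a)), diceCoefficient(a, a))
  expect_error(diceCoefficient(a, matrix(TRUE, 4, 4)), "same shape")
})

test_that("windowed SSIM matches the reference implementation on frozen cases", {
  i <- matrix(rep(1:48, 48), 48, 48)
  j <- t(i)
  x <- 0.5 + 0.4 * sin(i / 3) * cos(j / 5)
  y <- pmin(pmax(x + 0.15 * sin((i + 2 * j) / 7), 0), 1)
  # reference values computed once with scikit-image structural_similarity
  expect_equal(windowedSSIM(x, y, 11), 0.8776740106131448, tolerance = 1e-6)
  x2 <- pmin(pmax(0.5 + 0.5 * sin(i * j / 40), 0), 1)
  y2 <- pmin(pmax(0.8 * x2 + 0.1 + 0.1 * cos(i / 2), 0), 1)
  expect_equal(windowedSSIM(x2, y2, 7), 0.9465167258125263, tolerance = 1e-6)
})

test_that("windowed SSIM identities and input validation", {
  set.seed(2)
  x <- matrix(runif(30 * 40), 30, 40)
  expect_equal(windowedSSIM(x, x), 1)
  expect_lt(windowedSSIM(x, 1 - x), 1)
  expect_error(windowedSSIM(x, x, 10), "odd")
  expect_error(windowedSSIM(x[1:8, 1:8], x[1:8, 1:8], 11), "smaller")
  expect_error(windowedSSIM(x, x[, 1:20]), "same shape")
})

test_that("Dice compensation rescales SSIM and flags out-of-range values", {
  expect_equal(as.numeric(compensatedSSIM(0.5, 1.0)), 0.5)
  expect_equal(as.numeric(compensatedSSIM(0.45, 0.9)), 0.5)
  over <- compensatedSSIM(0.9, 0.6)
  expect_equal(as.numeric(over), 1.5)
  expect_true(attr(over, "exceedsOne"))
  expect_warning(miss <- compensatedSSIM(0.5, 0), "undefined")
  expect_true(is.na(miss))
  # monotone: increasing in SSIM, decreasing in Dice
  expect_gt(as.numeric(compensatedSSIM(0.6, 0.8)),
            as.numeric(compensatedSSIM(0.5, 0.8)))
  expect_gt(as.numeric(compensatedSSIM(0.5, 0.7)),
            as.numeric(compensatedSSIM(0.5, 0.8)))
})

test_that("positive-cell ratios count gated cells", {
  tab <- data.frame(CD45 = c(1, 2, 3, 4, 5, 6, 7, 8))
  expect_equal(positiveCellRatio(tab, "CD45", 0), 1)
  expect_equal(positiveCellRatio(tab, "CD45", 10), 0)
  expect_equal(positiveCellRatio(tab, "CD45", 5), 0.375)
  expect_error(positiveCellRatio(tab[0, , drop = FALSE], "CD45", 1), "empty")
  expect_error(positiveCellRatio(tab, "panCK", 1), "panCK")
})

test_that("ratio correlation matches the closed-form Pearson estimate", {
  r1 <- correlateRatios(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(r1$r, 1)
  r2 <- correlateRatios(1:5 / 10, 5:1 / 10)
  expect_equal(r2$r, -1)
  set.seed(4)
  xr <- runif(20)
  yr <- 0.6 * xr + rnorm(20, sd = 0.05)
  res <- correlateRatios(xr, yr)
  manual <- sum((xr - mean(xr)) * (yr - mean(yr))) /
    sqrt(sum((xr - mean(xr))^2) * sum((yr - mean(yr))^2))
  expect_equal(res$r, manual, tolerance = 1e-12)
  expect_lt(res$pValue, 1e-6)
  expect_warning(z <- correlateRatios(rep(0.5, 4), runif(4)), "zero variance")
  expect_true(is.na(z$r))
  expect_error(correlateRatios(1:2, 1:2), "at least 3")
})

test_that("stain-pair evaluation combines Dice, SSIM and the compensation", {
  mp <- generateMaskPair(c(64, 64), 0.7, seed = 5)
  set.seed(6)
  real <- matrix(runif(64 * 64), 64, 64)
  virtual <- pmin(pmax(real + rnorm(64 * 64, sd = 0.05), 0), 1)
  out <- evaluateStainPairs(list(
    list(real = real, virtual = virtual, maskA = mp$maskA, maskB = mp$maskB,
         roiId = "roi1")
  ))
  expect_equal(nrow(out$perROI), 1L)
  expect_equal(out$perROI$dice, mp$dice)
  expect_equal(out$perROI$compensatedSSIM,
               out$perROI$ssim / out$perROI$dice, tolerance = 1e-12)
  expect_equal(out$medianCompensated, out$perROI$compensatedSSIM)
})
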