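test_that("candidate enumeration counts windows and satisfies the partition identity", {
  g <- generateTileGrid(smallSpec(1, tiles = 8L))
  pr <- enumerateCandidates(g, 4, 4)
  expect_equal(ncol(pr@A), 4L)
  expect_equal(colSums(pr@A), rep(1, 4), tolerance = 1e-12)
  # pooling all non-overlapping candidates reproduces the slide composition
  expect_equal(rowMeans(pr@A), pr@b, tolerance = 1e-12)
  # overlapping stride enumerates (8-4+1)^2 windows
  pr1 <- enumerateCandidates(g, 4, 1)
  expect_equal(ncol(pr1@A), 25L)
  expect_error(enumerateCandidates(g, 9), "exceeds")
})

test_that("a homogeneous grid yields identical candidate columns with zero entropy", {
  g <- buildGridFromLabelMap(PixelLabelMap(matrix(1L, 256, 256)), 32)
  pr <- enumerateCandidates(g, 2, 2)
  expect_true(all(pr@A == pr@b))
  expect_equal(pr@E, rep(0, ncol(pr@A)))
})

test_that("L1 selection finds exact matches and exact two-column combinations", {
  A <- randomColumns(7, 10, seed = 1)
  prob <- problemFromColumns(A, b = A[, 4], epsilon = 1e-6)
  r <- selectL1(prob)
  expect_equal(selectedSupport(r), 4L)
  expect_equal(r@supportObjective, 1)
  expect_lte(r@objective, 1 + 1e-6)

  b2 <- 0.5 * A[, 2] + 0.5 * A[, 9]
  r2 <- selectL1(problemFromColumns(A, b = b2, epsilon = 1e-6))
  expect_equal(selectedSupport(r2), c(2L, 9L))
  expect_equal(r2@epsilonUsed, 1e-6)
})

test_that("infeasible L1 problems double the slack and eventually error", {
  A <- matrix(c(1, 0, 0, 0, 1, 0), 3, 2) # no column carries cluster 3
  b <- c(0.5, 0.3, 0.2)
  prob <- problemFromColumns(A, b = b, epsilon = 1e-4)
  expect_message(r <- selectL1(prob), "doubling epsilon")
  expect_gt(r@epsilonUsed, 1e-4)
  # a target far outside the reachable hull errors with a diagnostic
  Afar <- matrix(c(1, 0, 0, 1, 0, 0), 3, 2)
  expect_error(
    suppressMessages(selectL1(problemFromColumns(Afar, b = c(0, 0, 1),
                                                 epsilon = 1e-6))),
    "closest achievable"
  )
})

test_that("entropy selection reduces to least squares at lambda 0", {
  A <- randomColumns(7, 10, seed = 2)
  prob <- problemFromColumns(A, b = A[, 6])
  r <- selectEntropy(prob, lambda = 0)
  expect_equal(selectedSupport(r), 6L)
  expect_lt(r@objective, 1e-10)
  expect_lt(r@supportObjective, 1e-10)
})

test_that("duplicated columns give permutation-equivalent selections at lambda 0", {
  A <- randomColumns(5, 6, seed = 3)
  A[, 4] <- A[, 2] # duplicate
  prob <- problemFromColumns(A, b = A[, 2])
  r <- selectEntropy(prob, lambda = 0)
  expect_true(all(selectedSupport(r) %in% c(2L, 4L)))
  expect_lt(r@supportObjective, 1e-10)
})

test_that("the entropy weight steers the selection toward heterogeneous regions", {
  g <- generateTileGrid(smallSpec(11, tiles = 8L))
  pr <- enumerateCandidates(g, 2, 2)
  r0 <- selectEntropy(pr, lambda = 0)
  r1 <- selectEntropy(pr, lambda = 1)
  expect_gte(mean(pr@E[selectedSupport(r1)]),
             mean(pr@E[selectedSupport(r0)]) - 1e-12)
})

test_that("random selection is reproducible, non-overlapping and degenerate at k = M", {
  g <- generateTileGrid(smallSpec(12, tiles = 8L))
  pr <- enumerateCandidates(g, 4, 4) # 4 non-overlapping candidates
  rs <- randomSelection(pr, k = 4, nDraws = 50, seed = 1)
  expect_true(all(vapply(rs$draws, function(S) identical(S, 1:4), logical(1))))
  expect_equal(var(rs$metrics$mse), 0)

  pr2 <- enumerateCandidates(g, 4, 2) # overlapping candidate set
  rs2 <- randomSelection(pr2, k = 2, nDraws = 100, seed = 7)
  rs2b <- randomSelection(pr2, k = 2, nDraws = 100, seed = 7)
  expect_identical(rs2$draws, rs2b$draws)
  cand <- pr2@candidates
  for (S in rs2$draws[1:10]) {
    expect_false(sparseROI:::windowsOverlap(as.list(cand[S[1], ]),
                                            as.list(cand[S[2], ])))
  }
})

test_that("random-baseline composition error shrinks as more ROIs are drawn", {
  g <- generateTileGrid(smallSpec(13, tiles = 12L))
  pr <- enumerateCandidates(g, 2, 2) # 36 non-overlapping candidates
  m2 <- mean(randomSelection(pr, k = 2, nDraws = 200, seed = 5)$metrics$mse)
  m9 <- mean(randomSelection(pr, k = 9, nDraws = 200, seed = 5)$metrics$mse)
  expect_lt(m9, m2)
})

test_that("the exhaustive oracle counts supports and honours its budget", {
  A <- randomColumns(4, 4, seed = 4)
  prob <- problemFromColumns(A, b = rowMeans(A))
  bf <- bruteForceSelect(prob, maxK = 2, objective = "entropy")
  expect_equal(bf$nEvaluated, 10L) # C(4,1) + C(4,2)
  big <- problemFromColumns(randomColumns(3, 40, seed = 5))
  expect_error(bruteForceSelect(big, maxK = 20), "budget")
})

test_that("greedy de-overlap returns pairwise non-overlapping windows", {
  g <- generateTileGrid(smallSpec(14, tiles = 8L))
  pr <- enumerateCandidates(g, 4, 2)
  res <- new("SelectionResult",
    x = rep(0.5, ncol(pr@A)), support = seq_len(ncol(pr@A)),
    objective = 0, supportObjective = 0, status = "optimal",
    threshold = 0.01, epsilonUsed = NA_real_, method = "entropy", lambda = 1
  )
  d <- greedyDeoverlap(pr, res)
  S <- selectedSupport(d)
  cand <- pr@candidates
  for (i in seq_along(S)) for (j in seq_len(i - 1L)) {
    expect_false(sparseROI:::windowsOverlap(as.list(cand[S[i], ]),
                                            as.list(cand[S[j], ])))
  }
  expect_lt(length(S), ncol(pr@A))
})
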