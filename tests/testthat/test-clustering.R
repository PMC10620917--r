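test_that("k-means recovers constructed partitions and handles degeneracy", {
  expect_equal(kmeansTiles(matrix(rnorm(20), 10, 2), 1), rep(1L, 10))

  set.seed(2)
  cloud <- rbind(matrix(rnorm(60, mean = 0, sd = 0.1), 30, 2),
                 matrix(rnorm(60, mean = 10, sd = 0.1), 30, 2))
  lab <- kmeansTiles(cloud, 2, seed = 0)
  expect_equal(length(unique(lab[1:30])), 1L)
  expect_equal(length(unique(lab[31:60])), 1L)
  expect_false(lab[1] == lab[31])

  same <- matrix(1, 8, 3)
  expect_warning(labs <- kmeansTiles(same, 3), "duplicate centroids")
  expect_equal(labs, rep(1L, 8))
})

test_that("elbow selection recovers the generating cluster count", {
  set.seed(4)
  k0 <- 5L
  centers <- 10 * rbind(diag(4), rep(1, 4)) # pairwise far apart
  X <- centers[rep(seq_len(k0), each = 40), ] + matrix(rnorm(k0 * 40 * 4, sd = 0.3),
                                                       k0 * 40, 4)
  el <- elbowSelectK(X, 2:9, seed = 0)
  expect_equal(el$k, k0)
  expect_false(el$lowConfidence)
  el2 <- elbowSelectK(X, 2:9, seed = 0)
  expect_identical(el$withinSS, el2$withinSS)

  single <- matrix(rnorm(400), 100, 4)
  elS <- elbowSelectK(single, 2:9, seed = 0)
  expect_true(elS$lowConfidence)
  expect_error(elbowSelectK(X, 2:3), "at least 3")
})

test_that("purity matches hand-computed values and its invariances", {
  expect_equal(clusterPurity(1:7, 1:7), 1)
  expect_equal(clusterPurity(rep(1, 4), c(1, 1, 2, 2)), 0.5)
  expect_equal(clusterPurity(c(1, 1, 2, 2), c(1, 1, 1, 2)), 0.75)
  expect_error(clusterPurity(integer(0), integer(0)), "empty")

  set.seed(9)
  for (i in 1:10) {
    pred <- sample(1:4, 60, replace = TRUE)
    truth <- sample(1:3, 60, replace = TRUE)
    p0 <- clusterPurity(pred, truth)
    # relabeling invariance on both sides
    expect_equal(clusterPurity(c(5, 9, 2, 7)[pred], c(3, 1, 8)[truth]), p0)
    # splitting a predicted cluster never decreases purity
    split <- pred
    inC <- which(pred == 1)
    split[sample(inC, length(inC) %/% 2)] <- 99
    expect_gte(clusterPurity(split, truth), p0)
  }
})

test_that("NMI matches its formula cases and a frozen reference value", {
  expect_equal(nmi(c(1, 1, 2, 2), c(7, 7, 3, 3)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  expect_equal(nmi(rep(1, 5), rep(2, 5)), 1)   # two trivial partitions
  expect_equal(nmi(rep(1, 5), c(1, 1, 2, 2, 2)), 0)
  pred <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 0, 1, 1, 2, 0, 0, 1, 2, 2, 1, 0)
  truth <- c(1, 1, 1, 2, 2, 2, 1, 2, 2, 1, 1, 2, 2, 1, 2, 1, 1, 2, 2, 1)
  expect_equal(nmi(pred, truth), 0.1960863484740259, tolerance = 1e-12)
  expect_equal(nmi(pred, truth, average = "geometric"), 0.2012558105724586,
               tolerance = 1e-12)
})

test_that("NMI agrees with an independent contingency-table implementation", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    u <- sample(seq_len(sample(2:6, 1)), n, replace = TRUE)
    v <- sample(seq_len(sample(2:6, 1)), n, replace = TRUE)
    expect_equal(nmi(u, v), refNMI(u, v), tolerance = 1e-10)
    # permutation invariance
    expect_equal(nmi(max(u) + 1 - u, v), nmi(u, v), tolerance = 1e-12)
  }
})

test_that("Spearman pairing recovers permutations and beats greedy search", {
  set.seed(3)
  P <- matrix(runif(5 * 7), 5, 7)
  idt <- pairClustersSpearman(P, P)
  expect_equal(idt$assignment, 1:5)
  expect_equal(unname(diag(idt$correlation)), rep(1, 5))

  perm <- c(3, 1, 4, 5, 2)
  pr <- pairClustersSpearman(P[perm, ], P)
  expect_equal(pr$assignment, perm)

  # optimal assignment matches exhaustive search over all 3! pairings
  for (i in 1:10) {
    A <- matrix(runif(3 * 6), 3, 6)
    B <- matrix(runif(3 * 6), 3, 6)
    res <- pairClustersSpearman(A, B)
    cm <- res$correlation
    perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    scores <- vapply(perms, function(p) sum(cm[cbind(1:3, p)]), numeric(1))
    expect_equal(sum(cm[cbind(1:3, res$assignment)]), max(scores),
                 tolerance = 1e-12)
  }

  flat <- rbind(rep(1, 4), c(1, 2, 3, 4))
  expect_true(any(is.na(pairClustersSpearman(flat, flat)$correlation)))
})

test_that("canonical correlations behave under identity, affine maps and noise", {
  set.seed(6)
  X <- matrix(rnorm(200 * 4), 200, 4)
  self <- canonicalCorrelation(X, X, 2)
  expect_equal(self$correlations, c(1, 1), tolerance = 1e-8)

  # invariance under invertible affine transforms
  Tmat <- matrix(rnorm(16), 4, 4) + diag(4)
  Y <- matrix(rnorm(200 * 3), 200, 3)
  c1 <- canonicalCorrelation(X, Y, 2)
  c2 <- canonicalCorrelation(sweep(X %*% Tmat, 2, c(1, -2, 3, 0), "+"), Y, 2)
  expect_equal(c1$correlations, c2$correlations, tolerance = 1e-6)

  # independent data: close to the permutation-null quantiles
  nullCors <- replicate(20, canonicalCorrelation(X[sample(200), ], Y, 2)$correlations[1])
  expect_lt(c1$correlations[1], max(nullCors) + 0.1)
})

test_that("evaluateClustering aggregates the agreement metrics", {
  g <- generateTileGrid(smallSpec(2))
  lab <- kmeansTiles(compositions(g), 7, seed = 0)
  ev <- evaluateClustering(lab, tileLabels(g), compositions(g),
                           X = compositions(g),
                           Y = compositions(g) %*% matrix(rnorm(21), 7, 3))
  expect_s4_class(ev, "ClusterEvaluation")
  expect_gt(ev@purity, 0.8)
  expect_gt(ev@nmi, 0.5)
  expect_equal(length(ev@canonicalCorrelations), 2L)
})
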