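# k-NN Gaussian graph and local weighted means.

test_that("weights follow the Gaussian formula on forced geometries", {
  # two points at distance 2, k = 1, gamma = 0.25
  g <- knnGraph(matrix(c(0, 2), ncol = 1), k = 1, gamma = 0.25)
  expect_equal(as.vector(g@weights), rep(exp(-1), 2))
  expect_equal(as.vector(g@neighbors), c(2L, 1L))

  # three collinear points at 0, 1, 10: both ends pick the middle point
  g <- knnGraph(matrix(c(0, 1, 10), ncol = 1), k = 1, gamma = 0.1)
  expect_equal(g@neighbors[1, ], 2L)
  expect_equal(g@neighbors[3, ], 2L)

  # duplicate points are legal and carry weight exp(0) = 1
  g <- knnGraph(matrix(c(0, 0, 5), ncol = 1), k = 1, gamma = 1)
  expect_equal(g@weights[1, 1], 1)
  expect_equal(g@neighbors[1, 1], 2L)  # tie-break: lowest index
})

test_that("neighbour sets match an exhaustive distance-sort oracle", {
  set.seed(11)
  X <- matrix(rnorm(20 * 3), 20, 3)
  g <- knnGraph(X, k = 5, gamma = 0.7)
  expect_equal(g@neighbors, bruteKnn(X, 5))
  D <- as.matrix(dist(X))
  expect_equal(g@weights,
               matrix(exp(-0.7 * D[cbind(rep(1:20, 5),
                                         as.vector(g@neighbors))]^2), 20, 5))
})

test_that("graph construction rejects invalid inputs", {
  expect_error(knnGraph(matrix(1, 1, 1), k = 1), "at least 2")
  expect_error(knnGraph(matrix(rnorm(6), 3, 2), k = 0), "positive integer")
  expect_error(knnGraph(matrix(c(1, NA, 2, 3), 2, 2), k = 1), "non-finite")
})

test_that("local weighted means follow the weighted-average definition", {
  # single neighbour: weights cancel, LWM is the neighbour itself
  X <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  g <- knnGraph(X, k = 1, gamma = 2)
  expect_equal(localWeightedMean(X, g), X[2:1, ])

  # identical points: LWM equals the point
  Xc <- matrix(1.5, 4, 2)
  expect_equal(localWeightedMean(Xc, knnGraph(Xc, k = 2, gamma = 1)), Xc)

  # three points, k = 2: hand evaluation of the weighted mean
  X3 <- matrix(c(0, 1, 3), ncol = 1)
  gamma <- 0.2
  g3 <- knnGraph(X3, k = 2, gamma = gamma)
  w12 <- exp(-gamma * 1); w13 <- exp(-gamma * 9)
  expect_equal(localWeightedMean(X3, g3)[1, 1],
               (w12 * 1 + w13 * 3) / (w12 + w13))
})

test_that("LWM rows stay inside the neighbour convex hull", {
  set.seed(4)
  X <- matrix(rnorm(15 * 3), 15, 3)
  g <- knnGraph(X, k = 4, gamma = 0.5)
  xh <- localWeightedMean(X, g)
  for (i in 1:15) {
    nb <- X[g@neighbors[i, ], , drop = FALSE]
    expect_true(all(xh[i, ] >= apply(nb, 2, min) - 1e-12))
    expect_true(all(xh[i, ] <= apply(nb, 2, max) + 1e-12))
  }
})

test_that("LWM Gram matches explicit input-space inner products (linear kernel)", {
  set.seed(5)
  X <- matrix(rnorm(12 * 2), 12, 2)
  g <- knnGraph(X, k = 3, gamma = 0.4)
  K <- tcrossprod(X)
  expect_equal(lwmGram(K, g), tcrossprod(X, localWeightedMean(X, g)),
               tolerance = 1e-10)

  # k = 1: column j of Kbar is column s(j) of K
  g1 <- knnGraph(X, k = 1, gamma = 0.4)
  Kb <- lwmGram(K, g1)
  for (j in 1:12) expect_equal(Kb[, j], K[, g1@neighbors[j, 1]])

  # orthonormal points: Kbar entries are the normalized neighbour weights
  Xo <- diag(4)
  go <- knnGraph(Xo, k = 2, gamma = 0.3)
  Kbo <- lwmGram(diag(4), go)
  norm <- go@weights / rowSums(go@weights)
  for (j in 1:4) for (s in 1:2)
    expect_equal(Kbo[go@neighbors[j, s], j], norm[j, s])
})

test_that("graph, LWM and LWM Gram are permutation-equivariant", {
  set.seed(6)
  X <- matrix(rnorm(10 * 2), 10, 2)
  p <- sample(10)
  g <- knnGraph(X, k = 3, gamma = 0.5)
  gp <- knnGraph(X[p, ], k = 3, gamma = 0.5)
  expect_equal(localWeightedMean(X, g)[p, ], localWeightedMean(X[p, ], gp))
  K <- gramMatrix(X, X, kernelSpec("rbf", width = 0.5))
  expect_equal(lwmGram(K, g)[p, p], lwmGram(K[p, p], gp))
})

test_that("weights decay monotonically with distance at fixed gamma", {
  set.seed(7)
  for (r in 1:20) {
    d <- sort(runif(2, 0.1, 5))
    gamma <- runif(1, 0.1, 2)
    expect_gt(exp(-gamma * d[1]^2), exp(-gamma * d[2]^2))
  }
  # and on a concrete graph: weight order mirrors distance order
  X <- matrix(rnorm(8 * 2), 8, 2)
  g <- knnGraph(X, k = 4, gamma = 0.8)
  for (i in 1:8) expect_true(all(diff(g@weights[i, ]) <= 1e-15))
})

test_that("out-of-sample LWM reproduces the training path and brute force", {
  set.seed(8)
  Xt <- matrix(rnorm(12 * 2), 12, 2)
  g <- knnGraph(Xt, k = 3, gamma = 0.6)
  # a training point queried as new data: self-copy excluded
  expect_equal(lwmForNew(Xt[3, , drop = FALSE], Xt, 3, 0.6),
               localWeightedMean(Xt, g)[3, , drop = FALSE])
  # equidistant pair, k = 2: equally weighted mean
  Xs <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)
  expect_equal(as.vector(lwmForNew(matrix(c(1, 1), 1), Xs, 2, 0.5)),
               c(1, 0))
  # random queries vs exhaustive neighbour search
  Xn <- matrix(rnorm(5 * 2), 5, 2)
  got <- lwmForNew(Xn, Xt, 3, 0.6)
  for (i in 1:5) {
    d2 <- colSums((t(Xt) - Xn[i, ])^2)
    nb <- order(d2)[1:3]
    w <- exp(-0.6 * d2[nb])
    expect_equal(got[i, ], colSums(Xt[nb, ] * w) / sum(w))
  }
  expect_error(lwmForNew(matrix(1, 1, 3), Xt, 2, 0.6), "dimension")
})
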