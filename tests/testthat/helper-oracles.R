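# Independent oracles used across the suite.  These deliberately avoid the
# package's own linear-algebra paths: brute-force enumeration, scalar
# loops, generic numeric minimization.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive k-NN by full pairwise distance sort (ties: lowest index).
bruteKnn <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  t(vapply(seq_len(n), function(i) {
    ord <- order(D[i, ])
    ord[ord != i][seq_len(k)]
  }, integer(k)))
}

# Scalar-loop evaluation of the joint objective (membership exponent 2).
scalarObjective <- function(alpha, V, K, Kbar, codes, lambda, lambdaS, C,
                            hard = FALSE) {
  n <- length(codes); M <- nrow(alpha)
  f <- function(i) sapply(1:M, function(m) sum(alpha[m, ] * K[, i]))
  fb <- function(i) sapply(1:M, function(m) sum(alpha[m, ] * Kbar[, i]))
  onehot <- function(m) { v <- numeric(M); v[m] <- 1; v }
  total <- 0
  ui <- 0
  for (i in 1:n) {
    if (codes[i] >= 0) {
      y <- onehot(codes[i] + 1)
      total <- total + sum((f(i) - y)^2) + lambdaS * sum((fb(i) - y)^2)
    } else {
      ui <- ui + 1
      for (m in 1:M) {
        w2 <- V[ui, m]^2
        total <- total + w2 * sum((f(i) - onehot(m))^2) +
          lambdaS * w2 * sum((fb(i) - onehot(m))^2)
        if (!hard && w2 > 0)
          total <- total + C * (w2 * log(w2) - w2)
      }
    }
  }
  for (m in 1:M) for (i in 1:n) for (j in 1:n)
    total <- total + lambda * alpha[m, i] * K[i, j] * alpha[m, j]
  total
}

# A random small semi-supervised instance for property runs.
smallInstance <- function(seed, nMax = 30, dMax = 5, mMax = 3) {
  set.seed(seed)
  n <- sample(8:nMax, 1); d <- sample(2:dMax, 1); M <- sample(2:mMax, 1)
  X <- matrix(rnorm(n * d), n, d)
  codes <- rep(-1L, n)
  lab <- sample(n, M + sample(0:3, 1))
  codes[lab] <- c(0:(M - 1), sample(0:(M - 1), length(lab) - M, replace = TRUE))
  u <- sum(codes == -1L)
  K <- gramMatrix(X, X, kernelSpec("rbf", width = 0.5))
  g <- knnGraph(X, 3, gamma = 0.3)
  list(X = X, codes = codes, M = M, u = u, K = K, graph = g,
       Kbar = lwmGram(K, g), V = matrix(runif(u * M), u, M))
}

# Decision-step objective (no entropy term) as a function of vec(alpha),
# for generic numeric minimization.
decisionObjective <- function(avec, inst, lambda, lambdaS, V = inst$V) {
  a <- matrix(avec, inst$M, nrow(inst$X))
  scalarObjectiveFast(a, V, inst$K, inst$Kbar, inst$codes, lambda, lambdaS)
}

# Vectorized variant of the Eq-5-type objective (still independent of the
# solver: no shared system matrix, direct term evaluation).
scalarObjectiveFast <- function(alpha, V, K, Kbar, codes, lambda, lambdaS) {
  M <- nrow(alpha)
  fX <- t(alpha %*% K); fL <- t(alpha %*% Kbar)
  lab <- which(codes >= 0); unlab <- which(codes == -1)
  Y <- matrix(0, length(lab), M); Y[cbind(seq_along(lab), codes[lab] + 1)] <- 1
  total <- sum((fX[lab, , drop = FALSE] - Y)^2) +
    lambdaS * sum((fL[lab, , drop = FALSE] - Y)^2) +
    lambda * sum(alpha * (alpha %*% K))
  for (m in seq_len(M)) {
    cm <- numeric(M); cm[m] <- 1
    d1 <- rowSums(sweep(fX[unlab, , drop = FALSE], 2, cm)^2)
    d2 <- rowSums(sweep(fL[unlab, , drop = FALSE], 2, cm)^2)
    total <- total + sum(V[, m]^2 * (d1 + lambdaS * d2))
  }
  total
}
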