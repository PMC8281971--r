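# Core estimator: initialization, closed-form updates, objective, fit loop,
# prediction.

test_that("membership initialization fixes labelled one-hots and zeros the rest", {
  ini <- initMembership(c(0L, 1L, -1L, -1L))
  expect_equal(ini$Vl, diag(2))
  expect_equal(ini$Vu, matrix(0, 2, 2))
  ini3 <- initMembership(c(0L, 1L, 2L, -1L))
  expect_equal(ini3$Vl[3, ], c(0, 0, 1))
  expect_error(initMembership(c(0L, 0L, -1L, 2L)), "class 1 has no")
})

test_that("single labelled point reduces to scalar ridge", {
  # argmin (a - 1)^2 + lambda a^2  =>  a = 1/(1 + lambda)
  K <- matrix(1, 1, 1)
  a <- solveDecision(K, K, codes = 0L, V = matrix(0, 0, 1),
                     lambda = 1, lambdaS = 0)
  expect_equal(as.vector(a), 0.5)
})

test_that("zero memberships and lambdaS reduce to kernel ridge on labels", {
  set.seed(21)
  X <- matrix(rnorm(10 * 2), 10, 2)
  codes <- c(0L, 1L, 0L, 1L, rep(-1L, 6))
  K <- gramMatrix(X, X, kernelSpec("rbf", width = 0.5))
  g <- knnGraph(X, 3, gamma = 0.3)
  al <- solveDecision(K, lwmGram(K, g), codes, matrix(0, 6, 2),
                      lambda = 0.4, lambdaS = 0)
  # textbook kernel ridge on an all-labelled problem: alpha = Y (K + lambda I)^-1
  Xl <- X[1:4, ]; Kl <- K[1:4, 1:4]
  Y <- matrix(0, 2, 4); Y[cbind(codes[1:4] + 1, 1:4)] <- 1
  ridge <- Y %*% solve(Kl + 0.4 * diag(4))
  all4 <- solveDecision(Kl, Kl, codes[1:4], matrix(0, 0, 2),
                        lambda = 0.4, lambdaS = 0)
  expect_equal(all4, ridge, tolerance = 1e-8)
  # and with unlabelled expansion points, scoring the labelled block agrees
  expect_equal(t(al %*% K)[1:4, ], t(ridge %*% Kl)[, ],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("the decision solve is a stationary point and beats perturbations", {
  for (seed in c(31, 32, 33)) {
    inst <- smallInstance(seed)
    al <- solveDecision(inst$K, inst$Kbar, inst$codes, inst$V,
                        lambda = 0.5, lambdaS = 0.3)
    gr <- decisionGradient(al, inst$K, inst$Kbar, inst$codes, inst$V,
                           lambda = 0.5, lambdaS = 0.3)
    expect_lt(sqrt(sum(gr^2)), 1e-6 * (1 + sqrt(sum(al^2))))
    base <- decisionObjective(as.vector(al), inst, 0.5, 0.3)
    set.seed(seed + 100)
    for (r in 1:50) {
      pert <- as.vector(al) + rnorm(length(al), sd = 0.05)
      expect_lte(base, decisionObjective(pert, inst, 0.5, 0.3) + 1e-10)
    }
  }
  expect_error(solveDecision(diag(2), diag(2), c(0L, -1L),
                             matrix(0, 1, 1), lambda = 0), "positive")
})

test_that("membership update matches its closed form and limits", {
  # f at the class code on both routes: membership 1
  f <- matrix(c(1, 0), 1, 2)
  expect_equal(updateMembership(f, f, C = 2, lambdaS = 0.7)[1, 1], 1)
  # both squared distances 1, lambdaS = 1, C = 1: exp(-1)
  f1 <- matrix(c(1, -1), 1, 2)   # ||f - c_1||^2 = 1
  expect_equal(updateMembership(f1, f1, C = 1, lambdaS = 1)[1, 1], exp(-1))
  # far from every code: vanishing membership in all classes
  far <- matrix(c(50, -50), 1, 2)
  expect_lt(max(updateMembership(far, far, C = 1, lambdaS = 0.5)), 1e-100)
  expect_error(updateMembership(f, f, C = 0, lambdaS = 0), "positive")
})

test_that("membership update minimizes the per-element subproblem", {
  set.seed(41)
  for (r in 1:50) {
    d1 <- runif(1, 0, 6); d2 <- runif(1, 0, 6)
    ls <- runif(1, 0, 2); C <- runif(1, 0.2, 5)
    # realize the distances with 1-D-style score vectors
    fX <- matrix(c(1 - sqrt(d1), 0), 1, 2)   # ||f - c_1||^2 = d1
    fL <- matrix(c(1 - sqrt(d2), 0), 1, 2)
    w <- updateMembership(fX, fL, C, ls)[1, 1]
    g <- function(w) w^2 * (d1 + ls * d2) +
      C * (ifelse(w == 0, 0, w^2 * log(w^2)) - w^2)
    wopt <- optimize(g, c(0, 1), tol = 1e-10)$minimum
    expect_equal(w, wopt, tolerance = 1e-6)
  }
})

test_that("the objective agrees with a term-by-term scalar loop", {
  # zeros: F = l (1 + lambdaS)
  inst <- smallInstance(51)
  l <- sum(inst$codes >= 0)
  a0 <- matrix(0, inst$M, nrow(inst$X))
  expect_equal(pcObjective(a0, matrix(0, inst$u, inst$M), inst$K, inst$Kbar,
                           inst$codes, 0.3, 0.7, 1.5), l * (1 + 0.7))
  # random alpha/V vs the loop oracle
  set.seed(52)
  a <- matrix(rnorm(inst$M * nrow(inst$X), sd = 0.3), inst$M, nrow(inst$X))
  expect_equal(pcObjective(a, inst$V, inst$K, inst$Kbar, inst$codes,
                           0.3, 0.7, 1.5),
               scalarObjective(a, inst$V, inst$K, inst$Kbar, inst$codes,
                               0.3, 0.7, 1.5),
               tolerance = 1e-10)
  # a unit membership with its f-distances realized contributes -C through
  # entropy: n = 3 (two labelled, one unlabelled), alpha = 0, V = (1, 0)
  K3 <- diag(3)
  F <- pcObjective(matrix(0, 2, 3), matrix(c(1, 0), 1, 2), K3, K3,
                   c(0L, 1L, -1L), lambda = 0.3, lambdaS = 0.5, C = 2)
  # labelled: 2 (1 + 0.5); unlabelled V^2-weighted loss (1 + 0.5);
  # entropy: C (1 ln 1 - 1) = -2
  expect_equal(F, 3 + 1.5 - 2)
})

test_that("fitting two separated 1-D classes labels every point correctly", {
  X <- matrix(c(0, 0.4, 0.8, 1.2, 10, 10.4, 10.8, 11.2), ncol = 1)
  lab <- c(0L, -1L, -1L, -1L, 1L, -1L, -1L, -1L)
  fit <- pcFit(X, lab, k = 2)
  expect_equal(predict(fit), c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
  expect_true(all(diff(objectiveTrace(fit)) <=
                  1e-10 * abs(objectiveTrace(fit)[-length(objectiveTrace(fit))])))
})

test_that("maxIter = 0 returns the labelled-only initialization", {
  set.seed(61)
  prob <- makeProblem(nClass = 2, nPerClass = 15, separation = 8,
                      nLabeledPerClass = 2, seed = 61)
  fit <- pcFit(prob$X, prob$labels, maxIter = 0, C = 1)
  K <- gramMatrix(prob$X, prob$X, kernelConfig(fit))
  Kb <- lwmGram(K, fit@graph)
  u <- sum(prob$labels == -1L)
  expect_equal(dualCoef(fit),
               solveDecision(K, Kb, prob$labels, matrix(0, u, 2),
                             lambda = 0.1, lambdaS = 0.1))
  expect_length(objectiveTrace(fit), 0)
  expect_false(isConverged(fit))
})

test_that("fit validates its inputs", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(pcFit(X, rep(0L, 10)), "no unlabelled")
  expect_error(pcFit(X, c(0L, rep(-1L, 9))), "at least two classes")
  expect_error(pcFit(X, c(0L, 2L, rep(-1L, 8))), "class 1 has no")
  expect_error(pcFit(matrix(1, 6, 2), c(0L, 1L, rep(-1L, 4))),
               "positive value")  # identical points: C resolves to 0
  expect_error(pcFit(X, c(0L, 1L, rep(-1L, 8)), epsilon = 0), "positive")
})

test_that("decision values equal the dual expansion", {
  prob <- makeProblem(nClass = 2, nPerClass = 10, separation = 6,
                      nLabeledPerClass = 2, seed = 71)
  fit <- pcFit(prob$X, prob$labels, C = 1)
  K <- gramMatrix(prob$X, prob$X, kernelConfig(fit))
  expect_equal(decisionValues(fit), t(dualCoef(fit) %*% K))
  # scalar-loop oracle on new points
  Xn <- matrix(rnorm(6), 3, 2)
  got <- decisionValues(fit, Xn)
  Kc <- gramMatrix(prob$X, Xn, kernelConfig(fit))
  for (i in 1:3) for (m in 1:2)
    expect_equal(got[i, m], sum(dualCoef(fit)[m, ] * Kc[, i]))
  # zero coefficients give zero scores
  fit0 <- fit; fit0@alpha[] <- 0
  expect_equal(unique(as.vector(decisionValues(fit0, Xn))), 0)
})

test_that("argmax prediction breaks ties toward the lowest class code", {
  expect_equal(hardAssign(matrix(c(0.5, 0.5), 1, 2),
                          matrix(c(0.5, 0.5), 1, 2), 0), 0L)
  expect_equal(possclass:::argmaxCode(matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2,
                                             byrow = TRUE)),
               c(0L, 0L))
})

test_that("decision and membership predictions coincide at lambdaS = 0", {
  prob <- makeProblem(nClass = 3, nPerClass = 20, separation = 6,
                      nLabeledPerClass = 2, seed = 81)
  fit <- suppressWarnings(pcFit(prob$X, prob$labels, lambdaS = 0))
  expect_equal(predict(fit, by = "decision"), predict(fit, by = "membership"))
  Xn <- matrix(rnorm(20), 10, 2) * 2
  expect_equal(predict(fit, Xn, by = "decision"),
               predict(fit, Xn, by = "membership"))
})

test_that("memberships stay in (0,1] and suppress out-of-sample outliers (sharp C)", {
  prob <- makeProblem(nClass = 2, nPerClass = 25, separation = 10,
                      nLabeledPerClass = 4, seed = 91)
  fit <- suppressWarnings(pcFit(prob$X, prob$labels, C = 0.5))
  W <- membershipValues(fit)
  expect_true(all(W > 0) && all(W <= 1))
  # shell outliers scored out of sample: low membership in EVERY class
  ctr <- colMeans(prob$X)
  r <- 4 * max(sqrt(rowSums(sweep(prob$X, 2, ctr)^2)))
  theta <- seq(0, 2 * pi, length.out = 9)[-9]
  Xout <- cbind(ctr[1] + r * cos(theta), ctr[2] + r * sin(theta))
  mxOut <- apply(membershipValues(fit, Xout), 1, max)
  mxIn <- apply(W, 1, max)[prob$labels == -1L]
  expect_lt(max(mxOut), min(mxIn))
})

test_that("random initialization of memberships is honoured and reproducible", {
  prob <- makeProblem(nClass = 2, nPerClass = 15, separation = 8,
                      nLabeledPerClass = 2, seed = 95)
  f1 <- pcFit(prob$X, prob$labels, C = 1, init = "random", seed = 7)
  f2 <- pcFit(prob$X, prob$labels, C = 1, init = "random", seed = 7)
  expect_equal(dualCoef(f1), dualCoef(f2))
  expect_true(all(diff(objectiveTrace(f1)) <=
                  1e-10 * abs(objectiveTrace(f1)[-length(objectiveTrace(f1))])))
})

test_that("precomputed Gram fits match feature-space fits on the training set", {
  prob <- makeProblem(nClass = 2, nPerClass = 15, separation = 8,
                      nLabeledPerClass = 2, seed = 97)
  spec <- kernelSpec("rbf", width = 0.1)
  K <- gramMatrix(prob$X, prob$X, spec)
  ff <- pcFit(prob$X, prob$labels, kernel = spec, C = 1, gamma = 0.1, k = 3)
  fp <- pcFit(K, prob$labels, precomputed = TRUE, C = ff@hyper$C,
              gamma = ff@graph@gamma, k = 3)
  # same kernel metric need not give identical graphs (input-space vs
  # kernel-space distances differ for rbf), but predictions on cleanly
  # separated data agree
  expect_equal(predict(fp), predict(ff))
  expect_error(pcFit(K[, 1:10], prob$labels, precomputed = TRUE), "square")
})
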