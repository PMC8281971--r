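# Core estimator: alternating closed-form optimization of the decision
# function f(x) = alpha %*% k(x) and the possibilistic label memberships.
#
# With memberships fixed, the objective decouples across the M output
# coordinates of f into weighted regularized least squares: every row p of
# alpha solves  A a' = b_p  with the SAME symmetric system matrix
#   A = Kl Kl' + Ku S Ku' + lambdaS (Kbl Kbl' + Kbu S Kbu') + lambda K,
#   S = diag(sum_m w_m(x_j)^2),
# and right-hand sides
#   B = (Kl + lambdaS Kbl) Yl' + (Ku + lambdaS Kbu) (V^2),
# where Kl/Ku are the labelled/unlabelled column blocks of the Gram matrix,
# Kbl/Kbu those of the LWM Gram matrix, Yl the M x l one-hot targets and
# V^2 the elementwise-squared u x M membership block.  With f fixed, each
# membership has the closed-form exponential solved in updateMembership().

# System matrix and right-hand side of the decision step.  V: u x M.
.decisionSystem <- function(K, Kbar, codes, V, lambda, lambdaS) {
  info <- labelInfo(codes, requireUnlabeled = FALSE)
  if (nrow(V) != info$u || (info$u > 0L && ncol(V) != info$M))
    stop("membership block must be u x M", call. = FALSE)
  if (any(V < 0) || any(V > 1))
    stop("memberships must lie in [0, 1]", call. = FALSE)
  Kl <- K[, info$labeled, drop = FALSE]
  Kbl <- Kbar[, info$labeled, drop = FALSE]
  A <- tcrossprod(Kl) + lambdaS * tcrossprod(Kbl) + lambda * K
  B <- (Kl + lambdaS * Kbl) %*% t(info$Yl)
  if (info$u > 0L) {
    Ku <- K[, info$unlabeled, drop = FALSE]
    Kbu <- Kbar[, info$unlabeled, drop = FALSE]
    V2 <- V^2
    s <- rowSums(V2)
    A <- A + Ku %*% (s * t(Ku)) + lambdaS * (Kbu %*% (s * t(Kbu)))
    B <- B + (Ku + lambdaS * Kbu) %*% V2
  }
  list(A = (A + t(A)) / 2, B = B)
}

#' Closed-form decision-function update
#'
#' For fixed memberships, returns the dual coefficients \eqn{\alpha} that
#' zero the gradient of the joint objective, i.e. its exact minimizer.  If
#' the direct solve fails, a jitter of \code{1e-10 * trace(K)/n} is added to
#' the diagonal and finally a least-squares solve is used (with a warning).
#'
#' @param K \code{n x n} training Gram matrix.
#' @param Kbar \code{n x n} LWM Gram matrix from [lwmGram()].
#' @param codes 0-based label codes, \code{-1} for unlabelled.
#' @param V \code{u x M} membership block of the unlabelled instances
#'   (entries in \eqn{[0,1]}); an all-zero block reduces the solve to
#'   (LWM-regularized) kernel ridge on the labelled instances only.
#' @param lambda ridge penalty \eqn{\lambda > 0}.
#' @param lambdaS LWM-consistency weight \eqn{\lambda_s \ge 0}.
#' @return numeric \code{M x n} dual coefficient matrix.
#' @seealso [decisionGradient()] to verify stationarity.
#' @export
solveDecision <- function(K, Kbar, codes, V, lambda, lambdaS = 0) {
  if (!is.numeric(lambda) || lambda <= 0)
    stop("'lambda' must be positive", call. = FALSE)
  if (!is.numeric(lambdaS) || lambdaS < 0)
    stop("'lambdaS' must be non-negative", call. = FALSE)
  sys <- .decisionSystem(K, Kbar, codes, V, lambda, lambdaS)
  sol <- tryCatch(solve(sys$A, sys$B), error = function(e) NULL)
  if (is.null(sol)) {
    jitter <- 1e-10 * sum(diag(K)) / nrow(K)
    Aj <- sys$A + diag(jitter, nrow(sys$A))
    sol <- tryCatch(solve(Aj, sys$B), error = function(e) NULL)
  }
  if (is.null(sol)) {
    # The system is consistent (right-hand side lies in the range of the
    # Gram matrix), so the minimum-norm least-squares solution is still an
    # exact stationary point; the objective is flat along the null space.
    warning("ill-conditioned decision system; using minimum-norm least-squares solution",
            call. = FALSE)
    sv <- svd(sys$A)
    keep <- sv$d > max(sv$d) * 1e-12
    sol <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% sys$B) / sv$d[keep])
  }
  if (!all(is.finite(sol)))
    stopNumerical("decision solve produced non-finite coefficients")
  t(sol)
}

#' Gradient of the decision-step objective at alpha
#'
#' \code{2 * (alpha A - B')} for the quadratic decision-step objective;
#' the solver's output should make this (numerically) zero.
#'
#' @inheritParams solveDecision
#' @param alpha \code{M x n} dual coefficient matrix.
#' @return numeric \code{M x n} gradient matrix.
#' @export
decisionGradient <- function(alpha, K, Kbar, codes, V, lambda, lambdaS = 0) {
  sys <- .decisionSystem(K, Kbar, codes, V, lambda, lambdaS)
  2 * (alpha %*% sys$A - t(sys$B))
}

# Squared distances ||f_i - c_m||^2 between per-instance score vectors
# (rows of fX, one column per class) and the one-hot class codes c_m.
.codeDist2 <- function(fX) {
  M <- ncol(fX)
  sq <- rowSums(fX^2)
  # d2[i, m] = ||f_i||^2 - 2 f_im + 1
  matrix(sq, nrow(fX), M) - 2 * fX + 1
}

#' Closed-form membership update
#'
#' \deqn{w_m(x) = \exp\!\left(-\frac{\|f(x)-c_m\|^2 +
#'   \lambda_s\|f(\hat x)-c_m\|^2}{2C}\right)}
#' the exact per-element minimizer of the membership subproblem (squared
#' losses plus the fuzzy-entropy term).  Values lie in \eqn{(0, 1]};
#' distances large enough to underflow the exponential clamp to 0.
#'
#' @param fX numeric \code{m x M} decision values of the instances.
#' @param fLWM numeric \code{m x M} decision values of their LWMs.
#' @param C positive entropy balance parameter.
#' @param lambdaS LWM-consistency weight \eqn{\lambda_s \ge 0}.
#' @return numeric \code{m x M} membership matrix; rows are NOT constrained
#'   to sum to one (possibilistic relaxation), so an outlier far from every
#'   class code receives near-zero membership in all classes.
#' @export
updateMembership <- function(fX, fLWM, C, lambdaS = 0) {
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    stop("'C' must be positive", call. = FALSE)
  if (!identical(dim(fX), dim(fLWM)))
    stop("'fX' and 'fLWM' must have identical dimensions", call. = FALSE)
  exp(-(.codeDist2(fX) + lambdaS * .codeDist2(fLWM)) / (2 * C))
}

#' Hard one-hot assignment of unlabelled instances
#'
#' The exact minimizer of the hard-variant unlabelled terms for fixed
#' \eqn{f}: \eqn{y_j = \arg\min_m \|f(x_j)-c_m\|^2 +
#' \lambda_s\|f(\hat x_j)-c_m\|^2}, ties broken by the lowest class code.
#' At \eqn{\lambda_s = 0} this coincides with \eqn{\arg\max_m f_m(x_j)}.
#'
#' @inheritParams updateMembership
#' @return integer vector of 0-based class codes, one per row of \code{fX}.
#' @export
hardAssign <- function(fX, fLWM, lambdaS = 0) {
  if (!identical(dim(fX), dim(fLWM)))
    stop("'fX' and 'fLWM' must have identical dimensions", call. = FALSE)
  cost <- .codeDist2(fX) + lambdaS * .codeDist2(fLWM)
  argmaxCode(-cost)
}

#' Initial membership state
#'
#' Labelled instances get their fixed one-hot memberships, which are never
#' relaxed during the fit.  Unlabelled memberships start at zero (so the
#' first decision-function solve uses labelled data only) or, optionally,
#' uniform random values.
#'
#' @param codes 0-based label codes with \code{-1} for unlabelled.
#' @param init \code{"zeros"} (default) or \code{"random"}.
#' @return list with \code{Vl} (\code{l x M} one-hot block), \code{Vu}
#'   (\code{u x M} unlabelled block) and \code{M}.
#' @export
initMembership <- function(codes, init = c("zeros", "random")) {
  init <- match.arg(init)
  info <- labelInfo(codes, requireUnlabeled = FALSE)
  Vu <- if (init == "zeros") matrix(0, info$u, info$M)
        else matrix(runif(info$u * info$M), info$u, info$M)
  list(Vl = t(info$Yl), Vu = Vu, M = info$M)
}

#' Joint objective value
#'
#' Evaluates the full alternating-optimization objective with the
#' membership exponent fixed at 2: squared losses of the labelled
#' instances and their LWMs, membership-weighted squared losses of the
#' unlabelled instances and their LWMs, the RKHS ridge penalty
#' \eqn{\lambda\,\mathrm{tr}(\alpha K \alpha^T)}, and (soft variant only)
#' the fuzzy-entropy term \eqn{C \sum (w^2 \ln w^2 - w^2)} over unlabelled
#' instances with the convention \eqn{0 \ln 0 = 0}.  For the hard variant
#' \code{V} is the one-hot assignment and the entropy term is absent.
#'
#' @inheritParams solveDecision
#' @param alpha \code{M x n} dual coefficients.
#' @param C positive entropy balance parameter (ignored when
#'   \code{hard = TRUE}).
#' @param hard evaluate the hard-variant objective instead.
#' @return a single numeric objective value.
#' @export
pcObjective <- function(alpha, V, K, Kbar, codes, lambda, lambdaS, C,
                        hard = FALSE) {
  info <- labelInfo(codes, requireUnlabeled = FALSE)
  fX <- t(alpha %*% K)      # n x M scores
  fL <- t(alpha %*% Kbar)
  Ylr <- t(info$Yl)         # l x M
  lab <- info$labeled; unlab <- info$unlabeled
  F <- sum((fX[lab, , drop = FALSE] - Ylr)^2) +
    lambdaS * sum((fL[lab, , drop = FALSE] - Ylr)^2) +
    lambda * sum(alpha * t(fX))
  if (info$u > 0L) {
    d1 <- .codeDist2(fX[unlab, , drop = FALSE])
    d2 <- .codeDist2(fL[unlab, , drop = FALSE])
    V2 <- V^2
    F <- F + sum(V2 * d1) + lambdaS * sum(V2 * d2)
    if (!hard) {
      ent <- V2 * log(V2) - V2
      ent[V2 == 0] <- 0     # 0 ln 0 = 0
      F <- F + C * sum(ent)
    }
  }
  F
}

#' Fit the possibilistic semi-supervised kernel classifier
#'
#' Alternates the closed-form decision solve and the closed-form membership
#' update (or hard assignment), starting from labelled data only, until the
#' relative objective change falls below \code{epsilon} or \code{maxIter}
#' alternations have run.  The objective trace is non-increasing.
#'
#' @param X numeric feature matrix (instances x features), or the training
#'   Gram matrix when \code{precomputed = TRUE}.
#' @param labels integer vector of 0-based class codes with sentinel
#'   \code{-1} for unlabelled instances; every class needs at least one
#'   label and at least one instance must be unlabelled.
#' @param kernel a [KernelSpec-class]; \code{"auto"} widths resolve on
#'   \code{X}.
#' @param lambda ridge penalty \eqn{\lambda > 0}.
#' @param lambdaS LWM-consistency weight \eqn{\lambda_s \ge 0}.
#' @param C entropy balance parameter; \code{"auto"} (default) uses
#'   [divergenceC()], the mean distance of the instances from their
#'   centroid.  Identical instances make \code{"auto"} resolve to 0, which
#'   is rejected.
#' @param k neighbour count of the LWM graph.
#' @param gamma Gaussian width of the graph weights, or \code{"auto"}.
#' @param epsilon relative-change stopping threshold.
#' @param maxIter maximum alternations; \code{0} returns the labelled-only
#'   initialization.
#' @param hard fit the hard one-label-per-instance variant instead.
#' @param init initial unlabelled memberships: \code{"zeros"} or
#'   \code{"random"}.
#' @param precomputed treat \code{X} as a symmetric Gram matrix; the
#'   neighbour graph then uses the kernel-induced metric
#'   \eqn{d^2_{ij} = K_{ii} + K_{jj} - 2K_{ij}}.
#' @param seed optional seed for the \code{"random"} initialization.
#' @param verbose print the objective per iteration.
#' @return a fitted [PCModel-class].
#' @examples
#' prob <- makeProblem(nClass = 2, nPerClass = 30, separation = 8,
#'                     nLabeledPerClass = 2, seed = 1)
#' fit <- pcFit(prob$X, prob$labels)
#' mean(predict(fit)[prob$labels == -1] == prob$truth[prob$labels == -1])
#' @export
pcFit <- function(X, labels, kernel = kernelSpec("rbf"), lambda = 0.1,
                  lambdaS = 0.1, C = "auto", k = 5, gamma = "auto",
                  epsilon = 1e-3, maxIter = 50, hard = FALSE,
                  init = c("zeros", "random"), precomputed = FALSE,
                  seed = NULL, verbose = FALSE) {
  init <- match.arg(init)
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("'epsilon' must be positive", call. = FALSE)
  if (!is.numeric(maxIter) || maxIter < 0)
    stop("'maxIter' must be a non-negative integer", call. = FALSE)
  info <- labelInfo(labels)
  if (info$M < 2L)
    stop("classification needs at least two classes among the labelled instances",
         call. = FALSE)

  if (precomputed) {
    K <- .checkGram(X)
    if (nrow(K) != length(labels))
      stop("Gram matrix size does not match the label vector", call. = FALSE)
    kernel <- kernelSpec("precomputed", width = 1)
    graph <- .knnGraphFromGram(K, k, gamma)
    Xtrain <- K
    if (identical(C, "auto")) {
      # mean kernel-space distance from the centroid of the feature maps
      cm <- colMeans(K)
      C <- mean(sqrt(pmax(diag(K) - 2 * cm + mean(K), 0)))
    }
  } else {
    .checkFeatures(X)
    if (nrow(X) != length(labels))
      stop("feature matrix and label vector differ in length", call. = FALSE)
    kernel <- resolveKernel(kernel, X)
    graph <- knnGraph(X, k, gamma)
    K <- gramMatrix(X, X, kernel)
    Xtrain <- X
    if (identical(C, "auto")) C <- divergenceC(X)
  }
  if (!is.numeric(C) || C <= 0)
    stop("'C' must resolve to a positive value (identical instances give zero divergence)",
         call. = FALSE)
  Kbar <- lwmGram(K, graph)

  mem <- withSeed(seed, initMembership(labels, init))
  V <- mem$Vu
  hyper <- list(lambda = lambda, lambdaS = lambdaS, C = C, b = 2L,
                epsilon = epsilon, maxIter = as.integer(maxIter))

  # repeat the ill-conditioning warning at most once per fit
  warnedSingular <- FALSE
  solveStep <- function(V) withCallingHandlers(
    solveDecision(K, Kbar, labels, V, lambda, lambdaS),
    warning = function(w) {
      if (grepl("minimum-norm", conditionMessage(w))) {
        if (warnedSingular) invokeRestart("muffleWarning")
        warnedSingular <<- TRUE
      }
    })

  alpha <- solveStep(V)
  trace <- numeric(0)
  Fprev <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    if (iter > 1L) alpha <- solveStep(V)
    fX <- t(alpha %*% K)
    fL <- t(alpha %*% Kbar)
    if (hard) {
      y <- hardAssign(fX[info$unlabeled, , drop = FALSE],
                      fL[info$unlabeled, , drop = FALSE], lambdaS)
      V <- matrix(0, info$u, info$M)
      V[cbind(seq_len(info$u), y + 1L)] <- 1
    } else {
      V <- updateMembership(fX[info$unlabeled, , drop = FALSE],
                            fL[info$unlabeled, , drop = FALSE], C, lambdaS)
    }
    Fcur <- pcObjective(alpha, V, K, Kbar, labels, lambda, lambdaS, C, hard)
    if (!is.finite(Fcur))
      stopNumerical("objective became non-finite; check kernel and hyper-parameters")
    trace <- c(trace, Fcur)
    if (verbose)
      message(sprintf("iter %d: F = %.8g%s", iter, Fcur,
                      if (!is.null(Fprev))
                        sprintf(" (rel change %.3g)",
                                abs(Fcur - Fprev) / abs(Fprev)) else ""))
    if (!is.null(Fprev) &&
        (abs(Fprev) < 1e-12 || abs(Fcur - Fprev) < epsilon * abs(Fprev))) {
      converged <- TRUE
      break
    }
    Fprev <- Fcur
  }

  new("PCModel", alpha = alpha, Xtrain = Xtrain, kernel = kernel,
      graph = graph, codes = info$codes, M = info$M, hyper = hyper,
      membership = V, objectiveTrace = trace, converged = converged,
      hard = hard, precomputed = precomputed)
}

#' @rdname pcFit
#' @param ... passed on to [pcFit()].
#' @export
pcFitHard <- function(X, labels, ...) pcFit(X, labels, hard = TRUE, ...)
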