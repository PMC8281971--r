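# Prediction by the decision function and by the membership function, and
# the consistency diagnostics that compare the two routes.

# Training Gram and LWM Gram of a fitted model (recomputed on demand).
.trainGrams <- function(model) {
  K <- if (model@precomputed) model@Xtrain
       else gramMatrix(model@Xtrain, model@Xtrain, model@kernel)
  list(K = K, Kbar = lwmGram(K, model@graph))
}

# Decision values of instances and of their LWMs, rows = instances.
# Xnew = NULL scores the training set.
.modelScores <- function(model, Xnew = NULL) {
  if (is.null(Xnew)) {
    g <- .trainGrams(model)
    return(list(fX = t(model@alpha %*% g$K), fLWM = t(model@alpha %*% g$Kbar)))
  }
  if (model@precomputed)
    stop("out-of-sample scoring with a precomputed kernel requires feature inputs; refit on features",
         call. = FALSE)
  .checkFeatures(Xnew, n_min = 1L, arg = "Xnew")
  if (ncol(Xnew) != ncol(model@Xtrain))
    stop("'Xnew' feature dimension does not match the training data",
         call. = FALSE)
  Xhat <- lwmForNew(Xnew, model@Xtrain, model@graph@k, model@graph@gamma)
  list(fX = t(model@alpha %*% gramMatrix(model@Xtrain, Xnew, model@kernel)),
       fLWM = t(model@alpha %*% gramMatrix(model@Xtrain, Xhat, model@kernel)))
}

#' Decision-function values
#'
#' \eqn{f(x) = \alpha\,k(x)} with \eqn{k(x)} the cross-Gram vector against
#' the training instances; one score per class.
#'
#' @param model a fitted [PCModel-class].
#' @param Xnew numeric matrix of new instances; \code{NULL} (default)
#'   scores the training set.  With a precomputed kernel, a cross-Gram
#'   matrix (training rows x new columns) may be supplied instead.
#' @return numeric matrix, instances x classes.
#' @export
decisionValues <- function(model, Xnew = NULL) {
  stopifnot(is(model, "PCModel"))
  if (!is.null(Xnew) && model@precomputed) {
    if (!is.matrix(Xnew) || nrow(Xnew) != ncol(model@alpha))
      stop("with a precomputed kernel, 'Xnew' must be a cross-Gram matrix with one row per training instance",
           call. = FALSE)
    return(t(model@alpha %*% Xnew))
  }
  if (is.null(Xnew)) return(.modelScores(model)$fX)
  .checkFeatures(Xnew, n_min = 1L, arg = "Xnew")
  if (ncol(Xnew) != ncol(model@Xtrain))
    stop("'Xnew' feature dimension does not match the training data",
         call. = FALSE)
  t(model@alpha %*% gramMatrix(model@Xtrain, Xnew, model@kernel))
}

#' Membership-function values
#'
#' Applies the closed-form membership formula with the model's \code{C}
#' and \eqn{\lambda_s} to the decision values of each instance and of its
#' LWM (formed from the training neighbours for new instances).
#'
#' @inheritParams decisionValues
#' @return numeric matrix in \eqn{(0, 1]}, instances x classes; rows need
#'   not sum to one.
#' @export
membershipValues <- function(model, Xnew = NULL) {
  stopifnot(is(model, "PCModel"))
  s <- .modelScores(model, Xnew)
  updateMembership(s$fX, s$fLWM, model@hyper$C, model@hyper$lambdaS)
}

#' Predict class codes
#'
#' Argmax over classes of the decision values (\code{by = "decision"}) or
#' of the memberships (\code{by = "membership"}); ties break to the lowest
#' class code.  At \eqn{\lambda_s = 0} the two routes agree on every
#' instance.
#'
#' @param object a fitted [PCModel-class].
#' @param newdata new feature matrix, or \code{NULL} for the training set.
#' @param by \code{"decision"} or \code{"membership"}.
#' @param ... ignored.
#' @return integer vector of 0-based class codes.
#' @export
setMethod("predict", "PCModel",
          function(object, newdata = NULL, by = c("decision", "membership"),
                   ...) {
  by <- match.arg(by)
  scores <- if (by == "decision") decisionValues(object, newdata)
            else membershipValues(object, newdata)
  argmaxCode(scores)
})

#' Categorize instances by prediction-route consistency
#'
#' Value-level core of [classifyConsistency()].  An instance is
#' \code{"intrinsic"} when \eqn{f(x)} and \eqn{f(\hat x)} share the same
#' argmax; otherwise, with \eqn{m} the argmax of \eqn{f(x)}, it is
#' \code{"fake_consistent"} when \eqn{f_j(\hat x) - f_m(\hat x) <
#' (f_m(x) - f_j(x))/\lambda_s} for every \eqn{j \ne m} (the two routes
#' still predict the same class), else \code{"inconsistent"}.  At
#' \eqn{\lambda_s = 0} every instance is intrinsic by convention.
#'
#' @param fX numeric \code{m x M} decision values of the instances.
#' @param fLWM numeric \code{m x M} decision values of their LWMs.
#' @param lambdaS the LWM-consistency weight used by the fit.
#' @return character vector of categories.
#' @export
consistencyCategories <- function(fX, fLWM, lambdaS) {
  if (!identical(dim(fX), dim(fLWM)))
    stop("'fX' and 'fLWM' must have identical dimensions", call. = FALSE)
  m <- nrow(fX)
  if (lambdaS == 0) return(rep("intrinsic", m))
  pf <- argmaxCode(fX) + 1L
  pl <- argmaxCode(fLWM) + 1L
  out <- character(m)
  for (i in seq_len(m)) {
    if (pf[i] == pl[i]) { out[i] <- "intrinsic"; next }
    mi <- pf[i]
    j <- setdiff(seq_len(ncol(fX)), mi)
    fake <- all(fLWM[i, j] - fLWM[i, mi] < (fX[i, mi] - fX[i, j]) / lambdaS)
    out[i] <- if (fake) "fake_consistent" else "inconsistent"
  }
  out
}

#' Consistency diagnostics for a fitted model
#'
#' Compares the decision-function and membership-function predictions and
#' categorizes each instance (see [consistencyCategories()]).  The
#' prediction consistency rate is the fraction of instances on which the
#' two routes agree; the ground-truth consistency rate is the fraction of
#' intrinsic instances.
#'
#' @inheritParams decisionValues
#' @return a [ConsistencyReport-class].
#' @export
classifyConsistency <- function(model, Xnew = NULL) {
  stopifnot(is(model, "PCModel"))
  s <- .modelScores(model, Xnew)
  lambdaS <- model@hyper$lambdaS
  cats <- consistencyCategories(s$fX, s$fLWM, lambdaS)
  W <- updateMembership(s$fX, s$fLWM, model@hyper$C, lambdaS)
  predRate <- mean(argmaxCode(s$fX) == argmaxCode(W))
  new("ConsistencyReport", category = cats, predictionRate = predRate,
      groundTruthRate = mean(cats == "intrinsic"), lambdaS = lambdaS)
}

#' Consistency rates across a grid of LWM-consistency weights
#'
#' Refits the model for each \eqn{\lambda_s} value and records both
#' consistency rates on the training instances: small \eqn{\lambda_s}
#' drives the prediction rate to 1, and as \eqn{\lambda_s} grows,
#' fake-consistent instances turn inconsistent until the prediction rate
#' meets the ground-truth rate.
#'
#' @param X feature matrix.
#' @param labels 0-based label codes with \code{-1} for unlabelled.
#' @param lambdaS numeric vector of weights to sweep.
#' @param ... further arguments to [pcFit()].
#' @return data.frame with columns \code{lambdaS}, \code{predictionRate},
#'   \code{groundTruthRate}, \code{iterations}, \code{converged}.
#' @export
consistencySweep <- function(X, labels,
                             lambdaS = c(0, 0.001, 0.01, 0.1, 1, 10, 100, 1000),
                             ...) {
  rows <- lapply(lambdaS, function(ls) {
    fit <- pcFit(X, labels, lambdaS = ls, ...)
    rep <- classifyConsistency(fit)
    data.frame(lambdaS = ls,
               predictionRate = predictionConsistencyRate(rep),
               groundTruthRate = groundTruthConsistencyRate(rep),
               iterations = length(objectiveTrace(fit)),
               converged = isConverged(fit))
  })
  do.call(rbind, rows)
}
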