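#' Kernel configuration
#'
#' Describes one of the supported kernels, or an orthogonal multi-kernel
#' combination of several.  Widths may be the string \code{"auto"}, in which
#' case they are resolved from the data: the RBF \eqn{\gamma} becomes
#' \eqn{1/(2\bar d^2)} and the distance-kernel \eqn{\sigma} becomes
#' \eqn{1/\bar d}, with \eqn{\bar d} the mean pairwise Euclidean distance.
#'
#' @slot name one of \code{"linear"}, \code{"rbf"}, \code{"laplacian"},
#'   \code{"inverse_square_distance"}, \code{"inverse_distance"},
#'   \code{"precomputed"}, \code{"multi"}.
#' @slot width positive numeric width, or \code{NA_real_} while unresolved
#'   (\code{"auto"}).
#' @slot components list of \code{KernelSpec} for \code{"multi"}.
#' @seealso [kernelSpec()], [gramMatrix()]
#' @exportClass KernelSpec
setClass("KernelSpec",
         representation(name = "character", width = "numeric",
                        components = "list"),
         prototype(name = "rbf", width = NA_real_, components = list()))

.kernelNames <- c("linear", "rbf", "laplacian", "inverse_square_distance",
                  "inverse_distance", "precomputed", "multi")

setValidity("KernelSpec", function(object) {
  if (length(object@name) != 1L || !(object@name %in% .kernelNames))
    return(sprintf("unknown kernel '%s'", paste(object@name, collapse = ",")))
  if (length(object@width) != 1L)
    return("width must be a single value")
  if (!is.na(object@width) && object@width <= 0)
    return("width must be positive")
  if (object@name == "multi") {
    if (length(object@components) < 1L)
      return("multi kernel needs at least one component")
    ok <- vapply(object@components, function(s) is(s, "KernelSpec"), logical(1))
    if (!all(ok)) return("multi components must be KernelSpec objects")
    if (any(vapply(object@components, function(s) s@name == "multi", logical(1))))
      return("multi components cannot be nested multi kernels")
  }
  TRUE
})

#' k-nearest-neighbour graph with Gaussian weights
#'
#' For each instance the indices of its \code{k} nearest neighbours
#' (Euclidean distance, self excluded, ties broken by lowest index) and the
#' Gaussian weights \eqn{W_{sj} = \exp(-\gamma \|x_s - x_j\|^2)} attached to
#' them.  Neighbour row \code{i} lists the neighbourhood used to form the
#' local weighted mean of instance \code{i}.
#'
#' @slot k neighbour count actually used (\code{min(k, n - 1)}).
#' @slot gamma resolved Gaussian width \eqn{\gamma > 0}.
#' @slot neighbors integer matrix, \code{n x k}; row i = indices of the
#'   neighbours of instance i, nearest first.
#' @slot weights numeric matrix, \code{n x k}; matching Gaussian weights,
#'   all in (0, 1].
#' @slot n number of instances the graph was built on.
#' @seealso [knnGraph()], [localWeightedMean()], [lwmGram()]
#' @exportClass NeighborGraph
setClass("NeighborGraph",
         representation(k = "integer", gamma = "numeric",
                        neighbors = "matrix", weights = "matrix",
                        n = "integer"))

setValidity("NeighborGraph", function(object) {
  n <- object@n; k <- object@k
  if (length(k) != 1L || k < 1L) return("k must be a positive integer")
  if (length(object@gamma) != 1L || object@gamma <= 0)
    return("gamma must be positive")
  if (!identical(dim(object@neighbors), dim(object@weights)))
    return("neighbors and weights must have identical dimensions")
  if (nrow(object@neighbors) != n || ncol(object@neighbors) != k)
    return("neighbors must be an n x k matrix")
  idx <- as.vector(object@neighbors)
  if (any(idx < 1L) || any(idx > n)) return("neighbor index out of range")
  if (any(object@neighbors == row(object@neighbors)))
    return("self-loops are not allowed")
  if (any(object@weights <= 0) || any(object@weights > 1))
    return("weights must lie in (0, 1]")
  TRUE
})

#' Fitted possibilistic semi-supervised kernel classifier
#'
#' Holds the dual coefficients of the decision function, the training data
#' and graph needed to score new instances, the final label memberships of
#' the unlabelled training instances, and the objective trace of the
#' alternating optimization.
#'
#' @slot alpha numeric \code{M x n} dual coefficient matrix; the decision
#'   function is \eqn{f(x) = \alpha k(x)} with \eqn{k(x)} the cross-Gram
#'   vector against the training instances.
#' @slot Xtrain training feature matrix (or the training Gram matrix when
#'   \code{precomputed} is TRUE).
#' @slot kernel resolved [KernelSpec-class].
#' @slot graph [NeighborGraph-class] built on the training instances.
#' @slot codes 0-based training label codes (-1 = unlabelled).
#' @slot M number of classes.
#' @slot hyper named list: \code{lambda}, \code{lambdaS}, \code{C},
#'   \code{b} (fixed at 2), \code{epsilon}, \code{maxIter}.
#' @slot membership numeric \code{u x M} matrix of final memberships of the
#'   unlabelled training instances (one row per unlabelled instance).
#' @slot objectiveTrace objective value after each alternation.
#' @slot converged TRUE if the relative-change stopping rule fired before
#'   \code{maxIter}.
#' @slot hard TRUE for the hard-assignment variant.
#' @slot precomputed TRUE when \code{Xtrain} is a Gram matrix.
#' @seealso [pcFit()], [decisionValues()], [membershipValues()],
#'   [classifyConsistency()]
#' @exportClass PCModel
setClass("PCModel",
         representation(alpha = "matrix", Xtrain = "matrix",
                        kernel = "KernelSpec", graph = "NeighborGraph",
                        codes = "integer", M = "integer", hyper = "list",
                        membership = "matrix", objectiveTrace = "numeric",
                        converged = "logical", hard = "logical",
                        precomputed = "logical"))

setValidity("PCModel", function(object) {
  if (!all(is.finite(object@alpha))) return("alpha contains non-finite values")
  if (nrow(object@alpha) != object@M)
    return("alpha must have one row per class")
  if (ncol(object@alpha) != nrow(object@Xtrain))
    return("alpha must have one column per training instance")
  if (object@hyper$b != 2) return("the membership exponent b is fixed at 2")
  tr <- object@objectiveTrace
  if (length(tr) > 1L) {
    inc <- diff(tr) > 1e-10 * abs(tr[-length(tr)])
    if (any(inc)) return("objective trace is not non-increasing")
  }
  TRUE
})

#' Consistency diagnostics between the two prediction routes
#'
#' Categorizes instances by whether the decision-function prediction
#' (argmax of \eqn{f(x)}) and the membership-function prediction (argmax of
#' \eqn{w(x)}) agree and why: \emph{intrinsic} instances have the same
#' argmax for \eqn{f(x)} and \eqn{f(\hat x)} (the LWM); \emph{fake_consistent}
#' instances disagree there but still satisfy the margin inequality that
#' makes the two predictions coincide; remaining instances are
#' \emph{inconsistent} and flag unreliable, near-boundary predictions.
#'
#' @slot category character vector, one of \code{"intrinsic"},
#'   \code{"fake_consistent"}, \code{"inconsistent"} per instance.
#' @slot predictionRate fraction of instances with argmax \eqn{f} = argmax
#'   \eqn{w}.
#' @slot groundTruthRate fraction of intrinsic instances.
#' @slot lambdaS the LWM-consistency weight the report was computed under.
#' @seealso [classifyConsistency()], [consistencySweep()]
#' @exportClass ConsistencyReport
setClass("ConsistencyReport",
         representation(category = "character", predictionRate = "numeric",
                        groundTruthRate = "numeric", lambdaS = "numeric"))

setValidity("ConsistencyReport", function(object) {
  ok <- object@category %in% c("intrinsic", "fake_consistent", "inconsistent")
  if (!all(ok)) return("unknown consistency category")
  for (r in c(object@predictionRate, object@groundTruthRate))
    if (r < 0 || r > 1) return("rates must lie in [0, 1]")
  TRUE
})
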