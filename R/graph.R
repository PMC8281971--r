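# k-NN Gaussian graph and local weighted means (LWM).
#
# The LWM of instance i is the Gaussian-weighted average of its k nearest
# neighbours:  xhat_i = sum_{j in Ne(i)} W_ij x_j / sum_{j in Ne(i)} W_ij,
# W_ij = exp(-gamma ||x_i - x_j||^2).  Ne(i) never contains i itself.

# Core construction from a squared-distance matrix; gamma already numeric.
.graphFromDist2 <- function(D2, k, gamma) {
  n <- nrow(D2)
  k <- as.integer(min(k, n - 1L))
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    # order() is stable: equal distances resolve to the lowest index
    ord <- order(D2[i, ])
    nb[i, ] <- ord[ord != i][seq_len(k)]
  }
  w <- exp(-gamma * D2[cbind(rep(seq_len(n), k), as.vector(nb))])
  new("NeighborGraph", k = k, gamma = gamma, neighbors = nb,
      weights = matrix(w, n, k), n = n)
}

.resolveGamma <- function(gamma, dbar) {
  if (identical(gamma, "auto")) {
    if (dbar <= 0) return(1)  # degenerate: all points coincide
    return(1 / (2 * dbar^2))
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("'gamma' must be a positive number or \"auto\"", call. = FALSE)
  as.numeric(gamma)
}

#' Build the k-nearest-neighbour Gaussian-weight graph
#'
#' Neighbours are found by Euclidean distance with self excluded and
#' distance ties broken by the lowest instance index.  Edge weights are
#' \eqn{W_{ij} = \exp(-\gamma \|x_i - x_j\|^2)}; larger \eqn{\gamma} means a
#' narrower local scope.
#'
#' @param X numeric feature matrix, one row per instance (\eqn{n \ge 2}).
#' @param k number of neighbours (capped at \eqn{n - 1}).
#' @param gamma positive Gaussian width, or \code{"auto"} for
#'   \eqn{1/(2\bar d^2)} with \eqn{\bar d} the mean pairwise distance.
#' @return a [NeighborGraph-class].
#' @examples
#' X <- matrix(c(0, 2), ncol = 1)
#' g <- knnGraph(X, k = 1, gamma = 0.25)
#' g@weights  # exp(-0.25 * 4) = exp(-1)
#' @export
knnGraph <- function(X, k, gamma = "auto") {
  .checkFeatures(X)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k))
    stop("'k' must be a positive integer", call. = FALSE)
  D2 <- .crossDist2(X, X)
  gamma <- .resolveGamma(gamma, .meanPairwiseDist(X))
  .graphFromDist2(D2, k, gamma)
}

# Build a graph from a precomputed Gram matrix using the kernel-induced
# metric d^2(i, j) = K_ii + K_jj - 2 K_ij.
.knnGraphFromGram <- function(K, k, gamma = "auto") {
  d <- diag(K)
  D2 <- outer(d, d, "+") - 2 * K
  D2[D2 < 0] <- 0
  dbar <- mean(sqrt(D2[upper.tri(D2)]))
  .graphFromDist2(D2, k, .resolveGamma(gamma, dbar))
}

# Column-stochastic neighbour-weight matrix N (n x n): column j holds j's
# normalized neighbour weights, so that Xhat = t(N) %*% X and Kbar = K %*% N.
.normalizedWeightMatrix <- function(graph) {
  n <- graph@n; k <- graph@k
  norm <- graph@weights / rowSums(graph@weights)
  Matrix::sparseMatrix(i = as.vector(graph@neighbors),
                       j = rep(seq_len(n), k),
                       x = as.vector(norm), dims = c(n, n))
}

#' Local weighted means of each instance
#'
#' Row \code{i} of the result is the Gaussian-weighted average of the
#' neighbours of instance \code{i}; it always lies in the convex hull of
#' that neighbourhood.
#'
#' @param X the feature matrix the graph was built on.
#' @param graph a [NeighborGraph-class] built on \code{X}.
#' @return numeric \code{n x d} matrix of LWM points.
#' @export
localWeightedMean <- function(X, graph) {
  .checkFeatures(X)
  if (nrow(X) != graph@n)
    stop("'graph' was not built on 'X' (row count mismatch)", call. = FALSE)
  as.matrix(Matrix::crossprod(.normalizedWeightMatrix(graph), X))
}

#' LWM Gram matrix in kernel space
#'
#' \eqn{\bar K_{ij} = \langle\phi(x_i), \phi(\hat x_j)\rangle =
#' \sum_{s \in Ne(j)} W_{sj} K_{is} / \sum_{s \in Ne(j)} W_{sj}}; each
#' column of \eqn{\bar K} is a convex combination of columns of \eqn{K}, so
#' no feature-space coordinates are needed.
#'
#' @param K \code{n x n} Gram matrix over the instances of \code{graph}, in
#'   the same ordering.
#' @param graph a [NeighborGraph-class].
#' @return numeric \code{n x n} matrix \eqn{\bar K}.
#' @export
lwmGram <- function(K, graph) {
  if (!is.matrix(K) || nrow(K) != ncol(K))
    stop("'K' must be a square Gram matrix", call. = FALSE)
  if (nrow(K) != graph@n)
    stop("'K' and 'graph' cover different instance counts", call. = FALSE)
  as.matrix(K %*% .normalizedWeightMatrix(graph))
}

#' Local weighted means of new instances against a training set
#'
#' Each new point is averaged over its \code{k} nearest \emph{training}
#' instances with the training Gaussian width, so membership and
#' consistency diagnostics extend out of sample.  When a new point
#' coincides exactly with a training instance, one zero-distance copy is
#' excluded from its neighbour set, which reproduces the self-excluding
#' LWM the training path computes for that instance.
#'
#' @param Xnew numeric matrix of new instances.
#' @param Xtrain training feature matrix.
#' @param k neighbour count.
#' @param gamma positive Gaussian width (use the training value).
#' @return numeric \code{nrow(Xnew) x d} matrix of LWM points.
#' @export
lwmForNew <- function(Xnew, Xtrain, k, gamma) {
  .checkFeatures(Xnew, n_min = 1L, arg = "Xnew")
  .checkFeatures(Xtrain, n_min = 1L, arg = "Xtrain")
  if (ncol(Xnew) != ncol(Xtrain))
    stop("feature dimensions of 'Xnew' and 'Xtrain' differ", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0)
    stop("'gamma' must be positive", call. = FALSE)
  D2 <- .crossDist2(Xnew, Xtrain)
  out <- matrix(0, nrow(Xnew), ncol(Xtrain))
  for (i in seq_len(nrow(Xnew))) {
    ord <- order(D2[i, ])
    if (D2[i, ord[1L]] == 0)  # drop one exact duplicate (self-copy)
      ord <- ord[-1L]
    if (length(ord) == 0L)
      stop("no training neighbours available for instance ", i, call. = FALSE)
    nb <- ord[seq_len(min(k, length(ord)))]
    w <- exp(-gamma * D2[i, nb])
    out[i, ] <- colSums(Xtrain[nb, , drop = FALSE] * w) / sum(w)
  }
  out
}
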