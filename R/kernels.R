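# Kernel functions, multi-kernel combination and data-driven heuristics.

#' Create a kernel configuration
#'
#' @param name kernel family: \code{"linear"}, \code{"rbf"},
#'   \code{"laplacian"} (\eqn{\exp(-\sigma\|x-y\|)}),
#'   \code{"inverse_square_distance"} (\eqn{1/(1+\sigma\|x-y\|^2)}),
#'   \code{"inverse_distance"} (\eqn{1/(1+\sigma\|x-y\|)}),
#'   \code{"precomputed"}, or \code{"multi"}.
#' @param width positive width parameter (\eqn{\gamma} for rbf, \eqn{\sigma}
#'   for the distance kernels) or \code{"auto"} to resolve it from the data:
#'   with \eqn{\bar d} the mean pairwise Euclidean distance, rbf uses
#'   \eqn{\gamma = 1/(2\bar d^2)} and the distance kernels \eqn{\sigma =
#'   1/\bar d}.
#' @param components for \code{"multi"}, a list of component
#'   \code{KernelSpec} objects whose feature maps are concatenated
#'   orthogonally (their Grams are summed).
#' @return a [KernelSpec-class] object.
#' @examples
#' kernelSpec("rbf")
#' kernelSpec("multi", components = list(kernelSpec("linear"),
#'                                       kernelSpec("rbf", width = 0.5)))
#' @export
kernelSpec <- function(name = "rbf", width = "auto", components = list()) {
  if (!is.character(name) || length(name) != 1L || !(name %in% .kernelNames))
    stop(sprintf("unknown kernel name '%s'", paste(name, collapse = ",")),
         call. = FALSE)
  w <- if (identical(width, "auto")) NA_real_ else {
    if (!is.numeric(width) || length(width) != 1L || width <= 0)
      stop("kernel width must be a positive number or \"auto\"", call. = FALSE)
    as.numeric(width)
  }
  new("KernelSpec", name = name, width = w, components = components)
}

# Squared Euclidean cross-distances between the rows of A and B.
.crossDist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0   # guard tiny negatives from cancellation
  d2
}

.meanPairwiseDist <- function(X) {
  if (nrow(X) < 2L) return(1)
  mean(stats::dist(X))
}

# Resolve "auto" widths against data; returns a fully numeric KernelSpec.
resolveKernel <- function(spec, X) {
  stopifnot(is(spec, "KernelSpec"))
  if (spec@name == "multi") {
    spec@components <- lapply(spec@components, function(s) resolveKernel(s, X))
    return(spec)
  }
  if (spec@name %in% c("linear", "precomputed")) return(spec)
  if (is.na(spec@width)) {
    dbar <- .meanPairwiseDist(X)
    if (dbar <= 0) dbar <- 1   # all points identical: any width is equivalent
    spec@width <- if (spec@name == "rbf") 1 / (2 * dbar^2) else 1 / dbar
  }
  spec
}

#' Gram matrix between two sets of instances
#'
#' @param Xa,Xb numeric feature matrices with matching column counts
#'   (\code{Xb} defaults to \code{Xa}).
#' @param spec a [KernelSpec-class]; \code{"auto"} widths are resolved on
#'   \code{Xa}.
#' @return numeric \code{nrow(Xa) x nrow(Xb)} Gram matrix.  For
#'   \code{"multi"} the component Grams are summed (orthogonal feature-map
#'   concatenation).
#' @examples
#' X <- matrix(rnorm(12), 4, 3)
#' K <- gramMatrix(X, spec = kernelSpec("rbf", width = 0.5))
#' @export
gramMatrix <- function(Xa, Xb = Xa, spec = kernelSpec("rbf")) {
  .checkFeatures(Xa, n_min = 1L, arg = "Xa")
  .checkFeatures(Xb, n_min = 1L, arg = "Xb")
  if (ncol(Xa) != ncol(Xb))
    stop("feature dimensions of 'Xa' and 'Xb' differ", call. = FALSE)
  if (spec@name == "precomputed")
    stop("a precomputed kernel has no feature-space form; pass the Gram matrix directly",
         call. = FALSE)
  spec <- resolveKernel(spec, Xa)
  switch(spec@name,
    linear = tcrossprod(Xa, Xb),
    rbf = exp(-spec@width * .crossDist2(Xa, Xb)),
    laplacian = exp(-spec@width * sqrt(.crossDist2(Xa, Xb))),
    inverse_square_distance = 1 / (1 + spec@width * .crossDist2(Xa, Xb)),
    inverse_distance = 1 / (1 + spec@width * sqrt(.crossDist2(Xa, Xb))),
    multi = combineGrams(lapply(spec@components,
                                function(s) gramMatrix(Xa, Xb, s))))
}

#' Combine component Gram matrices orthogonally
#'
#' Concatenating the feature maps \eqn{\tilde\phi(x) = [\phi_1(x); \dots;
#' \phi_m(x)]} makes the combined kernel the elementwise sum of the
#' component kernels.
#'
#' @param grams non-empty list of numeric matrices of identical shape.
#' @return their elementwise sum.
#' @export
combineGrams <- function(grams) {
  if (!is.list(grams) || length(grams) < 1L)
    stop("'grams' must be a non-empty list of matrices", call. = FALSE)
  dims <- lapply(grams, dim)
  if (!all(vapply(dims, identical, logical(1), y = dims[[1L]])))
    stop("component Gram matrices differ in shape", call. = FALSE)
  Reduce(`+`, grams)
}

#' Data-divergence heuristic for the entropy balance parameter C
#'
#' \eqn{C = \sum_j \|x_j - \bar x\| / n}: the mean Euclidean distance of the
#' instances from their centroid.  Identical points give \eqn{C = 0}, which
#' the fit rejects (the membership exponential would be degenerate).
#'
#' @param X numeric feature matrix.
#' @return a non-negative scalar.
#' @examples
#' divergenceC(matrix(c(0, 2), ncol = 1))  # 1
#' @export
divergenceC <- function(X) {
  .checkFeatures(X, n_min = 1L)
  ctr <- colMeans(X)
  mean(sqrt(rowSums(sweep(X, 2L, ctr)^2)))
}

# Validate a user-supplied precomputed Gram matrix.
.checkGram <- function(K, tol = 1e-8) {
  if (!is.matrix(K) || !is.numeric(K) || nrow(K) != ncol(K))
    stop("a precomputed Gram matrix must be square and numeric", call. = FALSE)
  if (!all(is.finite(K)))
    stop("Gram matrix contains non-finite values", call. = FALSE)
  if (max(abs(K - t(K))) > tol * max(1, max(abs(K))))
    stop("Gram matrix is not symmetric within tolerance", call. = FALSE)
  (K + t(K)) / 2
}
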