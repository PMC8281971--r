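# Synthetic semi-supervised problems: Gaussian class blobs, scarce
# stratified labels, optional shell outliers.  Emulates the statistical
# setting the classifier assumes (clustered classes, few labels, noisy
# unlabelled pool) without any external data.

# Class centers with adjacent-center spacing separation * noiseSd:
# equally spaced on a line for d = 1, on a circle in the first two
# coordinates otherwise (remaining coordinates zero).
.blobCenters <- function(M, d, separation, noiseSd) {
  spacing <- separation * noiseSd
  centers <- matrix(0, M, d)
  if (d == 1L || M == 1L) {
    centers[, 1L] <- spacing * (seq_len(M) - 1L)
  } else {
    r <- spacing / (2 * sin(pi / M))
    ang <- 2 * pi * (seq_len(M) - 1L) / M
    centers[, 1L] <- r * cos(ang)
    centers[, 2L] <- r * sin(ang)
  }
  centers
}

#' Generate a synthetic semi-supervised classification problem
#'
#' Draws \code{nPerClass} Gaussian instances around each of \code{nClass}
#' centers whose adjacent spacing is \code{separation} within-class
#' standard deviations, keeps a small stratified set of labels and masks
#' the rest with the \code{-1} sentinel, and optionally appends unlabelled
#' outliers drawn uniformly on a shell at \code{outlierScale} times the
#' inlier data radius, so outliers are farther from every class center
#' than any inlier.
#'
#' Given a seed the output is reproducible; draws happen in a fixed order:
#' class points (class by class), labelled-index sampling (class by
#' class), then outlier directions and radii.
#'
#' @param nClass number of classes \eqn{M \ge 2}.
#' @param nPerClass instances per class.
#' @param d feature dimension.
#' @param separation adjacent center spacing in units of \code{noiseSd}.
#' @param noiseSd within-class standard deviation.
#' @param nLabeledPerClass labels kept per class (scalar or length-M
#'   vector); ignored when \code{nLabeledTotal} is given.
#' @param nLabeledTotal total labels, distributed round-robin over classes
#'   (class 0 first), so e.g. 10 labels over 3 classes gives 4/3/3.
#' @param outlierFraction outliers appended as a fraction of the inlier
#'   count, in \eqn{[0, 1)}.
#' @param outlierScale shell radius as a multiple of the inlier data
#'   radius (max distance from the inlier centroid).
#' @param seed optional integer seed.
#' @return list with \code{X} (feature matrix), \code{labels} (0-based
#'   codes, \code{-1} = unlabelled), \code{truth} (generating class per
#'   instance; \code{-1} for outliers, which belong to no class), and
#'   \code{outlier} (logical mask).
#' @examples
#' prob <- makeProblem(nClass = 3, nPerClass = 100, separation = 8,
#'                     nLabeledTotal = 10, seed = 1)
#' splitReport(prob$labels)
#' @export
makeProblem <- function(nClass = 3, nPerClass = 100, d = 2, separation = 8,
                        noiseSd = 1, nLabeledPerClass = 2,
                        nLabeledTotal = NULL, outlierFraction = 0,
                        outlierScale = 4, seed = NULL) {
  stopifnot(nClass >= 2, nPerClass >= 1, d >= 1, separation > 0, noiseSd > 0)
  if (outlierFraction < 0 || outlierFraction >= 1)
    stop("'outlierFraction' must lie in [0, 1)", call. = FALSE)
  if (!is.null(nLabeledTotal)) {
    if (nLabeledTotal < nClass)
      stop("'nLabeledTotal' must provide at least one label per class",
           call. = FALSE)
    nl <- tabulate((seq_len(nLabeledTotal) - 1L) %% nClass + 1L,
                   nbins = nClass)
  } else {
    nl <- rep_len(as.integer(nLabeledPerClass), nClass)
  }
  if (any(nl < 1L) || any(nl > nPerClass))
    stop("labelled counts must lie in [1, nPerClass]", call. = FALSE)

  withSeed(seed, {
    centers <- .blobCenters(nClass, d, separation, noiseSd)
    X <- do.call(rbind, lapply(seq_len(nClass), function(m) {
      sweep(matrix(rnorm(nPerClass * d, sd = noiseSd), nPerClass, d),
            2L, centers[m, ], "+")
    }))
    truth <- rep(seq_len(nClass) - 1L, each = nPerClass)
    labels <- rep(-1L, nrow(X))
    for (m in seq_len(nClass)) {
      idx <- which(truth == m - 1L)
      labels[sample(idx, nl[m])] <- m - 1L
    }
    outlier <- rep(FALSE, nrow(X))
    nOut <- round(outlierFraction * nrow(X))
    if (nOut > 0) {
      ctr <- colMeans(X)
      radius <- max(sqrt(rowSums(sweep(X, 2L, ctr)^2)))
      dir <- matrix(rnorm(nOut * d), nOut, d)
      dir <- dir / sqrt(rowSums(dir^2))
      Xout <- sweep(dir * (outlierScale * radius), 2L, ctr, "+")
      X <- rbind(X, Xout)
      truth <- c(truth, rep(-1L, nOut))
      labels <- c(labels, rep(-1L, nOut))
      outlier <- c(outlier, rep(TRUE, nOut))
    }
    list(X = X, labels = labels, truth = truth, outlier = outlier)
  })
}

#' Summarize the labelled/unlabelled split
#'
#' @param labels 0-based codes with \code{-1} for unlabelled.
#' @return list with \code{l} (labelled count), \code{u} (unlabelled
#'   count) and \code{perClass} (labelled count per class code).
#' @export
splitReport <- function(labels) {
  info <- labelInfo(labels, requireUnlabeled = FALSE)
  perClass <- tabulate(info$codes[info$labeled] + 1L, nbins = info$M)
  names(perClass) <- as.character(seq_len(info$M) - 1L)
  list(l = info$l, u = info$u, perClass = perClass)
}
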