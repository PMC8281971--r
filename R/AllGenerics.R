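#' @rdname PCModel-class
#' @param object,x a fitted model or report
#' @export
setGeneric("dualCoef", function(object) standardGeneric("dualCoef"))

#' @rdname PCModel-class
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))

#' @rdname PCModel-class
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname PCModel-class
#' @export
setGeneric("trainingMembership",
           function(object) standardGeneric("trainingMembership"))

#' @rdname PCModel-class
#' @export
setGeneric("kernelConfig", function(object) standardGeneric("kernelConfig"))

#' @rdname ConsistencyReport-class
#' @export
setGeneric("consistencyCategory",
           function(object) standardGeneric("consistencyCategory"))

#' @rdname ConsistencyReport-class
#' @export
setGeneric("predictionConsistencyRate",
           function(object) standardGeneric("predictionConsistencyRate"))

#' @rdname ConsistencyReport-class
#' @export
setGeneric("groundTruthConsistencyRate",
           function(object) standardGeneric("groundTruthConsistencyRate"))

setMethod("dualCoef", "PCModel", function(object) object@alpha)
setMethod("objectiveTrace", "PCModel", function(object) object@objectiveTrace)
setMethod("isConverged", "PCModel", function(object) object@converged)
setMethod("trainingMembership", "PCModel", function(object) object@membership)
setMethod("kernelConfig", "PCModel", function(object) object@kernel)

setMethod("consistencyCategory", "ConsistencyReport",
          function(object) object@category)
setMethod("predictionConsistencyRate", "ConsistencyReport",
          function(object) object@predictionRate)
setMethod("groundTruthConsistencyRate", "ConsistencyReport",
          function(object) object@groundTruthRate)

setMethod("show", "KernelSpec", function(object) {
  if (object@name == "multi") {
    cat(sprintf("Multi-kernel (%d components):\n", length(object@components)))
    for (s in object@components)
      cat(sprintf("  %s (width: %s)\n", s@name,
                  if (is.na(s@width)) "auto" else format(s@width)))
  } else {
    cat(sprintf("Kernel: %s (width: %s)\n", object@name,
                if (is.na(object@width)) "auto" else format(object@width)))
  }
  invisible(object)
})

setMethod("show", "NeighborGraph", function(object) {
  cat(sprintf("k-NN Gaussian graph: %d instances, k = %d, gamma = %.6g\n",
              object@n, object@k, object@gamma))
  invisible(object)
})

setMethod("show", "PCModel", function(object) {
  cat(sprintf("%s semi-supervised kernel classifier\n",
              if (object@hard) "Hard clustering-promoting"
              else "Possibilistic clustering-promoting"))
  li <- labelInfo(object@codes, object@M, requireUnlabeled = FALSE)
  cat(sprintf("  %d instances (%d labelled, %d unlabelled), %d classes, %d features\n",
              length(object@codes), li$l, li$u, object@M,
              if (object@precomputed) NA_integer_ else ncol(object@Xtrain)))
  cat(sprintf("  kernel: %s | k = %d, graph gamma = %.4g\n",
              object@kernel@name, object@graph@k, object@graph@gamma))
  h <- object@hyper
  cat(sprintf("  lambda = %.4g, lambdaS = %.4g, C = %.4g, b = %d\n",
              h$lambda, h$lambdaS, h$C, h$b))
  cat(sprintf("  %d iterations, %s (final objective %.6g)\n",
              length(object@objectiveTrace),
              if (object@converged) "converged" else "stopped at maxIter",
              tail(object@objectiveTrace, 1L)))
  invisible(object)
})

setMethod("show", "ConsistencyReport", function(object) {
  tab <- table(factor(object@category,
                      levels = c("intrinsic", "fake_consistent", "inconsistent")))
  cat(sprintf("Consistency report (lambdaS = %.4g, %d instances)\n",
              object@lambdaS, length(object@category)))
  cat(sprintf("  intrinsic: %d, fake-consistent: %d, inconsistent: %d\n",
              tab[1L], tab[2L], tab[3L]))
  cat(sprintf("  prediction consistency rate:   %.4f\n", object@predictionRate))
  cat(sprintf("  ground-truth consistency rate: %.4f\n", object@groundTruthRate))
  invisible(object)
})

#' @importFrom utils tail
NULL
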