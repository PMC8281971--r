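# Internal helpers shared across modules.

# Run an expression under a temporary RNG state.  NULL seed leaves the
# global stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Row-wise argmax with ties broken by the lowest column index; returns
# 0-based class codes.
argmaxCode <- function(scores) {
  stopifnot(is.matrix(scores))
  max.col(scores, ties.method = "first") - 1L
}

# Signal a numerical failure (distinct condition class so callers, e.g.
# the CLI, can map it to a dedicated exit code).
stopNumerical <- function(...) {
  stop(structure(class = c("possclass_numerical_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

.checkFeatures <- function(X, n_min = 2L, arg = "X") {
  if (!is.matrix(X) || !is.numeric(X))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (nrow(X) < n_min)
    stop(sprintf("'%s' needs at least %d rows, got %d", arg, n_min, nrow(X)),
         call. = FALSE)
  if (ncol(X) < 1L)
    stop(sprintf("'%s' needs at least one column", arg), call. = FALSE)
  if (!all(is.finite(X)))
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  invisible(X)
}

# Validate a semi-supervised label vector (0-based codes, -1 = unlabelled)
# and derive the bookkeeping every fit step needs.
labelInfo <- function(codes, nClass = NULL, requireUnlabeled = TRUE) {
  if (!is.numeric(codes) || any(codes != floor(codes)))
    stop("label codes must be integers", call. = FALSE)
  codes <- as.integer(codes)
  if (any(codes < -1L))
    stop("label codes must be >= -1 (-1 marks unlabelled instances)",
         call. = FALSE)
  labeled <- which(codes >= 0L)
  unlabeled <- which(codes == -1L)
  if (length(labeled) == 0L)
    stop("no labelled instances", call. = FALSE)
  M <- if (is.null(nClass)) max(codes) + 1L else as.integer(nClass)
  if (any(codes >= M))
    stop(sprintf("label code %d out of range for %d classes",
                 max(codes), M), call. = FALSE)
  present <- tabulate(codes[labeled] + 1L, nbins = M)
  if (any(present == 0L))
    stop(sprintf("class %d has no labelled instance",
                 which(present == 0L)[1L] - 1L), call. = FALSE)
  if (requireUnlabeled && length(unlabeled) == 0L)
    stop("no unlabelled instances: a semi-supervised fit needs at least one",
         call. = FALSE)
  # M x l one-hot targets for the labelled block
  Yl <- matrix(0, nrow = M, ncol = length(labeled))
  Yl[cbind(codes[labeled] + 1L, seq_along(labeled))] <- 1
  list(codes = codes, M = M, l = length(labeled), u = length(unlabeled),
       labeled = labeled, unlabeled = unlabeled, Yl = Yl)
}
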