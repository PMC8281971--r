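# Delimited-text feature/label I/O, JSON model serialization, and
# evaluation metrics.  Feature tables: one instance per row, comma or tab
# separated, optional header.  Label files: one integer per row, 0-based
# class codes with -1 for unlabelled.

.detectSep <- function(line) if (grepl("\t", line)) "\t" else ","

#' Read a feature matrix from delimited text
#'
#' @param path file path.
#' @param sep field separator: \code{","}, \code{"\\t"} or \code{"auto"}
#'   (default; tab if the first line contains one, else comma).
#' @param header skip a header line.
#' @return numeric matrix.  Ragged rows and non-numeric cells raise errors
#'   naming the offending row.
#' @export
readFeatures <- function(path, sep = "auto", header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (header) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no data rows in ", path, call. = FALSE)
  if (identical(sep, "auto")) sep <- .detectSep(lines[[1L]])
  fields <- strsplit(lines, sep, fixed = TRUE)
  d <- length(fields[[1L]])
  lens <- lengths(fields)
  if (any(lens != d))
    stop(sprintf("ragged row %d: %d fields, expected %d",
                 which(lens != d)[1L] + header, lens[lens != d][1L], d),
         call. = FALSE)
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) {
    bad <- ceiling(which(is.na(vals))[1L] / d)
    stop(sprintf("non-numeric value in row %d", bad + header), call. = FALSE)
  }
  matrix(vals, nrow = length(lines), ncol = d, byrow = TRUE)
}

#' Write a feature matrix as delimited text at full precision
#'
#' @param X numeric matrix.
#' @param path file path.
#' @param sep field separator.
#' @export
writeFeatures <- function(X, path, sep = ",") {
  stopifnot(is.matrix(X))
  rows <- apply(X, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = sep))
  writeLines(rows, path)
}

#' Read a label vector
#'
#' One integer per row: 0-based class codes, \code{-1} for unlabelled.
#'
#' @param path file path.
#' @param nClass optional class count; codes \code{>= nClass} raise a
#'   parse error.
#' @return integer vector.
#' @export
readLabels <- function(path, nClass = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(vals) | vals != floor(vals) | vals < -1)
  if (length(bad) > 0L)
    stop(sprintf("invalid label in row %d: '%s'", bad[1L], lines[bad[1L]]),
         call. = FALSE)
  if (!is.null(nClass) && any(vals >= nClass))
    stop(sprintf("label code %d in row %d out of range for %d classes",
                 max(vals), which.max(vals), nClass), call. = FALSE)
  as.integer(vals)
}

#' @rdname readLabels
#' @param labels integer label vector to write.
#' @export
writeLabels <- function(labels, path) {
  writeLines(as.character(as.integer(labels)), path)
}

#' Write predicted class codes (one per row)
#'
#' @param pred integer vector of 0-based codes.
#' @param path file path.
#' @export
writePredictions <- function(pred, path) writeLabels(pred, path)

#' Write a membership matrix as delimited text
#'
#' @param W numeric instances x classes matrix.
#' @inheritParams writeFeatures
#' @export
writeMemberships <- function(W, path, sep = ",") writeFeatures(W, path, sep)

#' Serialize a fitted model to JSON
#'
#' All numeric content is written at full precision, so a save/load
#' round-trip reproduces predictions bit for bit.  The document carries a
#' \code{format_version} field.
#'
#' @param model a fitted [PCModel-class].
#' @param path file path.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "PCModel"))
  doc <- list(
    format_version = 1L,
    hard = model@hard,
    precomputed = model@precomputed,
    M = model@M,
    codes = model@codes,
    alpha = model@alpha,
    Xtrain = model@Xtrain,
    kernel = .kernelToList(model@kernel),
    graph = list(k = model@graph@k, gamma = model@graph@gamma,
                 n = model@graph@n, neighbors = model@graph@neighbors,
                 weights = model@graph@weights),
    hyper = model@hyper,
    membership = model@membership,
    objectiveTrace = model@objectiveTrace,
    converged = model@converged)
  # 17 significant digits: doubles survive the text round trip bit-exactly
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE), path)
}

.kernelToList <- function(spec) {
  list(name = spec@name, width = spec@width,
       components = lapply(spec@components, .kernelToList))
}

.kernelFromList <- function(x) {
  new("KernelSpec", name = x$name, width = as.numeric(x$width),
      components = lapply(x$components, .kernelFromList))
}

#' @rdname writeModel
#' @return \code{readModel} returns the restored [PCModel-class].
#' @export
readModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(readLines(path), simplifyMatrix = TRUE)
  if (is.null(doc$format_version) || doc$format_version != 1L)
    stop("unsupported model format version", call. = FALSE)
  u <- sum(doc$codes == -1L)
  M <- as.integer(doc$M)
  graph <- new("NeighborGraph", k = as.integer(doc$graph$k),
               gamma = as.numeric(doc$graph$gamma),
               neighbors = matrix(as.integer(doc$graph$neighbors),
                                  nrow = doc$graph$n),
               weights = as.matrix(doc$graph$weights),
               n = as.integer(doc$graph$n))
  mem <- if (u > 0L) matrix(as.numeric(doc$membership), nrow = u, ncol = M)
         else matrix(0, 0L, M)
  hyper <- doc$hyper
  hyper$b <- as.integer(hyper$b)
  hyper$maxIter <- as.integer(hyper$maxIter)
  new("PCModel", alpha = as.matrix(doc$alpha), Xtrain = as.matrix(doc$Xtrain),
      kernel = .kernelFromList(doc$kernel), graph = graph,
      codes = as.integer(doc$codes), M = M, hyper = hyper,
      membership = mem, objectiveTrace = as.numeric(doc$objectiveTrace),
      converged = doc$converged, hard = doc$hard,
      precomputed = doc$precomputed)
}

#' Classification metrics
#'
#' @param pred integer predicted codes.
#' @param truth integer true codes.
#' @param mask optional logical vector; only \code{TRUE} positions are
#'   evaluated.
#' @return list with \code{accuracy}, \code{perClass} (accuracy per true
#'   class) and \code{confusion} (true x predicted count table).
#' @examples
#' evaluatePredictions(c(0, 1, 1), c(0, 1, 0))$accuracy
#' @export
evaluatePredictions <- function(pred, truth, mask = NULL) {
  if (length(pred) != length(truth))
    stop("'pred' and 'truth' differ in length", call. = FALSE)
  if (!is.null(mask)) {
    if (length(mask) != length(pred))
      stop("'mask' length mismatch", call. = FALSE)
    pred <- pred[mask]; truth <- truth[mask]
  }
  if (length(pred) == 0L) stop("no instances to evaluate", call. = FALSE)
  lev <- sort(unique(c(pred, truth)))
  conf <- table(truth = factor(truth, levels = lev),
                predicted = factor(pred, levels = lev))
  perClass <- diag(conf) / rowSums(conf)
  list(accuracy = mean(pred == truth),
       perClass = perClass[rowSums(conf) > 0],
       confusion = conf)
}
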