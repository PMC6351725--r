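#' Construct a FeatureExperiment
#'
#' Builds the central experiment object from an abundance matrix and
#' (optionally) metadata tables. Missing metadata tables are created
#' empty, keyed by the matrix dimnames; a matrix without dimnames gets
#' synthetic "S1..Sn" / "F1..Fm" identifiers.
#'
#' @param data numeric matrix, samples in rows, features in columns.
#'   Values must be non-negative.
#' @param sampleMetadata data.frame with one row per sample. Row names
#'   (or an explicit first-column key matching the matrix row names) are
#'   the sample identifiers.
#' @param featureMetadata data.frame with one row per feature, keyed by
#'   feature identifier.
#' @param sparse logical; store the matrix as a \code{Matrix} sparse
#'   matrix. Purely a storage hint: all operations give identical
#'   results for both storage modes.
#' @param experimentType "amplicon", "ms1" or "generic".
#' @return a validated \code{\linkS4class{FeatureExperiment}}.
#' @examples
#' m <- matrix(c(5, 0, 1, 3), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("fA", "fB")))
#' fe <- featureExperiment(m)
#' nSamples(fe)
#' @export
featureExperiment <- function(data, sampleMetadata = NULL,
                              featureMetadata = NULL, sparse = FALSE,
                              experimentType = c("generic", "amplicon", "ms1")) {
  experimentType <- match.arg(experimentType)
  if (is.null(rownames(data)))
    rownames(data) <- paste0("S", seq_len(nrow(data)))
  if (is.null(colnames(data)))
    colnames(data) <- paste0("F", seq_len(ncol(data)))
  if (is.null(sampleMetadata))
    sampleMetadata <- data.frame(row.names = rownames(data))
  if (is.null(featureMetadata))
    featureMetadata <- data.frame(row.names = colnames(data))
  if (!identical(rownames(sampleMetadata), rownames(data)))
    sampleMetadata <- sampleMetadata[rownames(data), , drop = FALSE]
  if (!identical(rownames(featureMetadata), colnames(data)))
    featureMetadata <- featureMetadata[colnames(data), , drop = FALSE]
  storage <- if (sparse) Matrix::Matrix(as.matrix(data), sparse = TRUE)
             else as.matrix(data)
  methods::new("FeatureExperiment",
    data = storage,
    sampleMetadata = sampleMetadata,
    featureMetadata = featureMetadata,
    sparse = sparse,
    experimentType = experimentType)
}

#' @describeIn featureExperiment abundance matrix; \code{dense = TRUE}
#'   (default) returns a base matrix regardless of storage.
#' @param x a FeatureExperiment.
#' @param dense return a dense base matrix.
#' @param ... unused.
#' @export
setMethod("abundance", "FeatureExperiment", function(x, dense = TRUE, ...) {
  if (dense) .denseData(x) else x@data
})

#' @describeIn featureExperiment sample metadata table.
#' @export
setMethod("sampleData", "FeatureExperiment", function(x) x@sampleMetadata)

#' @describeIn featureExperiment feature metadata table.
#' @export
setMethod("featureData", "FeatureExperiment", function(x) x@featureMetadata)

#' @describeIn featureExperiment sample identifiers.
#' @export
setMethod("sampleIds", "FeatureExperiment", function(x) rownames(x@sampleMetadata))

#' @describeIn featureExperiment feature identifiers.
#' @export
setMethod("featureIds", "FeatureExperiment", function(x) rownames(x@featureMetadata))

#' @describeIn featureExperiment number of samples.
#' @export
setMethod("nSamples", "FeatureExperiment", function(x) nrow(x@data))

#' @describeIn featureExperiment number of features.
#' @export
setMethod("nFeatures", "FeatureExperiment", function(x) ncol(x@data))

#' @describeIn featureExperiment per-sample total after TSS, or
#'   numeric(0) if unnormalized.
#' @export
setMethod("normalizedTotal", "FeatureExperiment", function(x) x@normalizedTotal)

#' @describeIn featureExperiment the recorded operation history.
#' @export
setMethod("opHistory", "FeatureExperiment", function(x) x@history)

#' @describeIn featureExperiment experiment type string.
#' @export
setMethod("experimentType", "FeatureExperiment", function(x) x@experimentType)

#' @describeIn featureExperiment replace the feature metadata (row count
#'   and order must match).
#' @param value replacement data.frame.
#' @export
setMethod("featureData<-", "FeatureExperiment", function(x, value) {
  stopifnot(is.data.frame(value), nrow(value) == nFeatures(x))
  rownames(value) <- featureIds(x)
  x@featureMetadata <- value
  methods::validObject(x)
  x
})

#' @describeIn featureExperiment replace the sample metadata.
#' @export
setMethod("sampleData<-", "FeatureExperiment", function(x, value) {
  stopifnot(is.data.frame(value), nrow(value) == nSamples(x))
  rownames(value) <- sampleIds(x)
  x@sampleMetadata <- value
  methods::validObject(x)
  x
})

setMethod("show", "FeatureExperiment", function(object) {
  cat(sprintf("FeatureExperiment (%s): %d samples x %d features\n",
              object@experimentType, nSamples(object), nFeatures(object)))
  if (length(object@normalizedTotal))
    cat(sprintf("  normalized per-sample total: %g\n", object@normalizedTotal))
  cat(sprintf("  storage: %s%s\n", if (object@sparse) "sparse" else "dense",
              if (object@nonCount) " (non-count values)" else ""))
  cat(sprintf("  sample metadata: %s\n",
              if (ncol(object@sampleMetadata)) paste(names(object@sampleMetadata), collapse = ", ") else "(none)"))
  cat(sprintf("  feature metadata: %s\n",
              if (ncol(object@featureMetadata)) paste(names(object@featureMetadata), collapse = ", ") else "(none)"))
  cat(sprintf("  history: %d operation(s)\n", length(object@history)))
})

setMethod("show", "DiffResult", function(object) {
  cat(sprintf("DiffResult: %d features tested, %d significant (alpha = %s, %s)\n",
              length(object@featureIds), sum(object@rejected),
              format(object@spec$alpha), object@spec$fdrMethod))
  if (!is.na(object@threshold))
    cat(sprintf("  dsFDR |statistic| threshold: %g\n", object@threshold))
})

setMethod("show", "AnnotationStore", function(object) {
  cat(sprintf("AnnotationStore: %d annotation(s) covering %d feature(s)\n",
              length(object@annotations), length(object@index)))
})

# ---- history ---------------------------------------------------------

#' Append an operation record to an experiment's history
#'
#' Every mutating operation in the package calls this once with its name
#' and full parameter set, so the whole exploratory process is tractable
#' and replayable. Parameters must be JSON-serializable.
#'
#' @param exp a FeatureExperiment.
#' @param opName operation name (a registered operation name enables
#'   \code{\link{replayHistory}}).
#' @param params named list of parameters.
#' @return the experiment with one more history record.
#' @export
recordHistory <- function(exp, opName, params = list()) {
  ok <- .jsonData(params) &&
    !is.null(tryCatch(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA,
                                       null = "null"),
                      error = function(e) NULL))
  if (!ok)
    .stopInvalid("history parameters for '%s' are not JSON-serializable", opName)
  rec <- list(op_name = opName, params = params,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"))
  exp@history <- c(exp@history, list(rec))
  exp
}

# internal shorthand used by operations
.recordOp <- function(exp, opName, params) recordHistory(exp, opName, params)

# Registry of replayable operations: history op_name -> function(exp, params).
.opRegistry <- new.env(parent = emptyenv())

.registerOp <- function(name, fn) assign(name, fn, envir = .opRegistry)

#' Replay a recorded operation history
#'
#' Applies the (operation, parameters) sequence recorded in \code{history}
#' to a pristine experiment, reproducing the derived experiment exactly.
#' All matrix-mutating operations of the package are registered; unknown
#' operation names raise an error.
#'
#' @param exp the pristine FeatureExperiment the history started from.
#' @param history a history list, e.g. \code{opHistory(derived)}.
#' @return the replayed FeatureExperiment.
#' @export
replayHistory <- function(exp, history) {
  for (rec in history) {
    fn <- get0(rec$op_name, envir = .opRegistry)
    if (is.null(fn))
      .stopInvalid("cannot replay unregistered operation '%s'", rec$op_name)
    exp <- fn(exp, rec$params)
  }
  exp
}

# ---- reorder / subset ------------------------------------------------

# Subset/permute one axis without recording history (shared primitive).
.subsetAxis <- function(exp, indexList, axis) {
  n <- if (axis == "samples") nSamples(exp) else nFeatures(exp)
  idx <- as.integer(indexList)
  if (length(idx) && (min(idx) < 1 || max(idx) > n))
    .stopInvalid("index out of range 1..%d on axis '%s'", n, axis)
  if (anyDuplicated(idx))
    .stopInvalid("duplicated indices in reorder on axis '%s'", axis)
  if (axis == "samples") {
    exp@data <- exp@data[idx, , drop = FALSE]
    exp@sampleMetadata <- exp@sampleMetadata[idx, , drop = FALSE]
  } else {
    exp@data <- exp@data[, idx, drop = FALSE]
    exp@featureMetadata <- exp@featureMetadata[idx, , drop = FALSE]
  }
  # an empty subset drops matrix dimnames to NULL; restore from metadata
  dimnames(exp@data) <- list(rownames(exp@sampleMetadata),
                             rownames(exp@featureMetadata))
  methods::validObject(exp)
  exp
}

#' Permute or subset an experiment along one axis
#'
#' The primitive under all sorting and filtering operations: returns a
#' new experiment whose matrix rows/columns and the corresponding
#' metadata rows are rearranged in the given order. Indices are 1-based
#' and must be unique; a subset of indices subsets the experiment.
#'
#' @param x a FeatureExperiment.
#' @param indexList integer vector of 1-based indices (possibly a
#'   subset, no duplicates).
#' @param axis "samples" or "features".
#' @param ... unused.
#' @return the reordered FeatureExperiment, history appended.
#' @export
setMethod("reorder", "FeatureExperiment",
  function(x, indexList, axis = c("samples", "features"), ...) {
    axis <- match.arg(axis)
    out <- .subsetAxis(x, indexList, axis)
    .recordOp(out, "reorder", list(indexList = as.integer(indexList), axis = axis))
  })

.registerOp("reorder", function(exp, params)
  reorder(exp, params$indexList, params$axis))
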