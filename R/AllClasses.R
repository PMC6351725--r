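#' FeatureExperiment: an abundance table joined with its metadata
#'
#' The central container of the package. It holds a samples x features
#' abundance matrix together with a sample-metadata table (one row per
#' matrix row) and a feature-metadata table (one row per matrix column),
#' and records every operation applied to it. All operations in the
#' package are non-mutating: they return a new \code{FeatureExperiment}
#' with the history extended, so an analysis can be replayed from the
#' pristine input (see \code{\link{replayHistory}}).
#'
#' Sample identifiers are the row names of \code{sampleMetadata} and the
#' row names of \code{data}; feature identifiers are the row names of
#' \code{featureMetadata} and the column names of \code{data}. The
#' validity method enforces that both axes stay synchronized after every
#' operation.
#'
#' @slot data numeric matrix (or \code{Matrix} sparse matrix) of
#'   non-negative abundances, samples in rows, features in columns.
#'   Transforms such as CLR may introduce negative values; the
#'   \code{nonCount} slot is then set.
#' @slot sampleMetadata data.frame keyed by sample id (row names).
#' @slot featureMetadata data.frame keyed by feature id (row names).
#' @slot sparse logical storage hint; results are identical for sparse
#'   and dense storage.
#' @slot normalizedTotal numeric(0) if unnormalized, otherwise the
#'   per-sample total after total-sum scaling (e.g. 10000).
#' @slot nonCount logical; TRUE after a transform (e.g. CLR) whose output
#'   is no longer on a count scale.
#' @slot history list of history records (name, params, timestamp).
#' @slot experimentType one of "amplicon" (feature ids are nucleotide
#'   sequences), "ms1" (feature ids encode m/z and retention time) or
#'   "generic".
#'
#' @seealso \code{\link{featureExperiment}} for the constructor,
#'   \code{\link{abundance}}, \code{\link{sampleData}},
#'   \code{\link{featureData}} for accessors.
#' @exportClass FeatureExperiment
setClass("FeatureExperiment",
  representation(
    data = "ANY",
    sampleMetadata = "data.frame",
    featureMetadata = "data.frame",
    sparse = "logical",
    normalizedTotal = "numeric",
    nonCount = "logical",
    history = "list",
    experimentType = "character"
  ),
  prototype(
    sparse = FALSE,
    normalizedTotal = numeric(0),
    nonCount = FALSE,
    history = list(),
    experimentType = "generic"
  )
)

.validFeatureExperiment <- function(object) {
  msg <- character(0)
  d <- object@data
  if (!(is.matrix(d) || methods::is(d, "Matrix")))
    msg <- c(msg, "data must be a base matrix or a Matrix sparse matrix")
  else {
    if (nrow(d) != nrow(object@sampleMetadata))
      msg <- c(msg, sprintf("sampleMetadata has %d rows but data has %d samples",
                            nrow(object@sampleMetadata), nrow(d)))
    if (ncol(d) != nrow(object@featureMetadata))
      msg <- c(msg, sprintf("featureMetadata has %d rows but data has %d features",
                            nrow(object@featureMetadata), ncol(d)))
    sid <- rownames(object@sampleMetadata)
    fid <- rownames(object@featureMetadata)
    if (anyDuplicated(sid)) msg <- c(msg, "duplicated sample identifiers")
    if (anyDuplicated(fid)) msg <- c(msg, "duplicated feature identifiers")
    # a zero-length axis stores its dimnames as NULL; treat as empty
    rn <- rownames(d); if (is.null(rn) && nrow(d) == 0) rn <- character(0)
    cn <- colnames(d); if (is.null(cn) && ncol(d) == 0) cn <- character(0)
    if (!identical(rn, sid))
      msg <- c(msg, "data row names do not match sampleMetadata row names")
    if (!identical(cn, fid))
      msg <- c(msg, "data column names do not match featureMetadata row names")
    if (!object@nonCount && nrow(d) > 0 && ncol(d) > 0 && min(d) < 0)
      msg <- c(msg, "abundance values must be non-negative")
  }
  if (!object@experimentType %in% c("amplicon", "ms1", "generic"))
    msg <- c(msg, "experimentType must be amplicon, ms1 or generic")
  if (length(object@normalizedTotal) > 1 ||
      (length(object@normalizedTotal) == 1 && object@normalizedTotal <= 0))
    msg <- c(msg, "normalizedTotal must be absent or a single positive number")
  if (length(msg)) msg else TRUE
}
setValidity("FeatureExperiment", .validFeatureExperiment)

#' DiffResult: per-feature permutation-test results
#'
#' Returned by \code{\link{diffAbundance}} and
#' \code{\link{correlationTest}}. Features are kept in the input order of
#' the experiment.
#'
#' @slot featureIds character, feature identifiers in input order.
#' @slot statObs numeric, observed per-feature statistic.
#' @slot pValues numeric in (0, 1], permutation p-values.
#' @slot qValues numeric, FDR-adjusted values (method-dependent).
#' @slot rejected logical, features declared significant.
#' @slot direction character; "group1"/"group2" for two-group tests
#'   (the group with the larger transformed mean), "pos"/"neg" for
#'   correlation tests.
#' @slot threshold numeric; the dsFDR statistic threshold when
#'   applicable, otherwise \code{NA_real_}.
#' @slot spec list; the full test specification (field, groups,
#'   transform, statistic, permutations, alpha, fdr method, seed, ...).
#' @exportClass DiffResult
setClass("DiffResult",
  representation(
    featureIds = "character",
    statObs = "numeric",
    pValues = "numeric",
    qValues = "numeric",
    rejected = "logical",
    direction = "character",
    threshold = "numeric",
    spec = "list"
  )
)

setValidity("DiffResult", function(object) {
  n <- length(object@featureIds)
  lens <- c(length(object@statObs), length(object@pValues),
            length(object@qValues), length(object@rejected),
            length(object@direction))
  if (any(lens != n)) return("all per-feature slots must have equal length")
  if (n > 0 && (any(object@pValues <= 0) || any(object@pValues > 1)))
    return("p-values must lie in (0, 1]")
  TRUE
})

#' AnnotationStore: a local store of ontology-term annotations
#'
#' A validated collection of annotation records, each tying a set of
#' feature identifiers to ontology terms with an annotation type, plus an
#' index from feature id to the annotations covering it. This is a local,
#' file-backed stand-in for curated annotation databases; the enrichment
#' statistics only see this interface, so other backends can be added
#' without touching the math.
#'
#' Each annotation is a list with elements \code{annotation_id},
#' \code{type} (one of higher_in, lower_in, common, high_freq,
#' contamination, other), \code{terms} (character, non-empty except for
#' contamination annotations), \code{experiment} and \code{features}
#' (character).
#'
#' @slot annotations named list of annotation records (by annotation id).
#' @slot index named list mapping feature id to the ids of annotations
#'   whose feature set contains it.
#' @exportClass AnnotationStore
setClass("AnnotationStore",
  representation(annotations = "list", index = "list"),
  prototype(annotations = structure(list(), names = character(0)),
            index = structure(list(), names = character(0)))
)

.annotationTypes <- c("higher_in", "lower_in", "common", "high_freq",
                      "contamination", "other")

setValidity("AnnotationStore", function(object) {
  ann <- object@annotations
  if (length(ann) && anyDuplicated(names(ann)))
    return("duplicated annotation ids")
  for (a in ann) {
    if (!all(c("annotation_id", "type", "terms", "features") %in% names(a)))
      return("annotation record missing required fields")
    if (!a$type %in% .annotationTypes)
      return(sprintf("unknown annotation type '%s'", a$type))
    if (a$type != "contamination" && length(a$terms) == 0)
      return(sprintf("annotation '%s' has no terms", a$annotation_id))
  }
  TRUE
})

#' HeatmapSpec: parameters of a heatmap rendering
#'
#' @slot sampleBarFields character; sample-metadata columns drawn as
#'   categorical color tracks above the heatmap.
#' @slot featureBarField character(0) or one feature-metadata column
#'   drawn as a color track to the right of the heatmap.
#' @slot colorScale "log" (display scale log2(x + cutoff), default) or
#'   "linear".
#' @slot logCutoff positive real added before the log display scale so
#'   zeros map to the colormap minimum.
#' @slot colormap name of a \code{grDevices::hcl.colors} palette.
#' @exportClass HeatmapSpec
setClass("HeatmapSpec",
  representation(
    sampleBarFields = "character",
    featureBarField = "character",
    colorScale = "character",
    logCutoff = "numeric",
    colormap = "character"
  ),
  prototype(
    sampleBarFields = character(0),
    featureBarField = character(0),
    colorScale = "log",
    logCutoff = 1,
    colormap = "Viridis"
  )
)

setValidity("HeatmapSpec", function(object) {
  if (!object@colorScale %in% c("log", "linear"))
    return("colorScale must be 'log' or 'linear'")
  if (length(object@logCutoff) != 1 || object@logCutoff <= 0)
    return("logCutoff must be a single positive number")
  if (length(object@featureBarField) > 1)
    return("featureBarField must be absent or a single column name")
  TRUE
})
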