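#' Filter samples or features by a metadata field
#'
#' Keeps exactly the rows/columns whose \code{field} value is in
#' \code{values} (or not in, with \code{negate = TRUE}); original order
#' is preserved. The two calls with \code{negate = FALSE} and
#' \code{negate = TRUE} partition the axis.
#'
#' @param exp a FeatureExperiment.
#' @param axis "samples" or "features".
#' @param field metadata column name on that axis.
#' @param values values to keep (or drop when negated).
#' @param negate complement the kept set.
#' @return the filtered experiment (possibly empty, with a warning).
#' @export
filterByMetadata <- function(exp, axis = c("samples", "features"),
                             field, values, negate = FALSE) {
  axis <- match.arg(axis)
  md <- if (axis == "samples") sampleData(exp) else featureData(exp)
  if (!field %in% names(md))
    .stopInvalid("field '%s' not found on axis '%s'; available: %s",
                 field, axis, paste(names(md), collapse = ", "))
  keep <- md[[field]] %in% values
  if (negate) keep <- !keep
  if (!any(keep))
    warning(sprintf("filterByMetadata kept 0 %s", axis))
  out <- .subsetAxis(exp, which(keep), axis)
  .recordOp(out, "filterByMetadata",
            list(axis = axis, field = field, values = values, negate = negate))
}
.registerOp("filterByMetadata", function(exp, params)
  suppressWarnings(filterByMetadata(exp, params$axis, params$field,
                                    unlist(params$values), isTRUE(params$negate))))

#' Filter features by total abundance across samples
#'
#' Keeps features whose total over all samples is \code{>= minTotal};
#' strictly smaller totals are filtered away. The threshold applies to
#' the matrix values as they currently are (e.g. run after TSS
#' normalization to filter on total normalized reads).
#'
#' @param exp a FeatureExperiment.
#' @param minTotal minimum total (boundary kept).
#' @return the filtered experiment.
#' @export
filterSumAbundance <- function(exp, minTotal) {
  totals <- colSums(.denseData(exp))
  keep <- which(totals >= minTotal)
  if (!length(keep)) warning("filterSumAbundance kept 0 features")
  out <- .subsetAxis(exp, keep, "features")
  .recordOp(out, "filterSumAbundance", list(minTotal = minTotal))
}
.registerOp("filterSumAbundance", function(exp, params)
  suppressWarnings(filterSumAbundance(exp, params$minTotal)))

#' Filter features by prevalence
#'
#' Keeps features present (value \code{> presenceCutoff}) in at least
#' \code{minFraction} of the samples; a feature present in exactly that
#' fraction is kept.
#'
#' @param exp a FeatureExperiment.
#' @param minFraction required fraction of samples, in (0, 1].
#' @param presenceCutoff value above which a feature counts as present.
#' @return the filtered experiment.
#' @export
filterPrevalence <- function(exp, minFraction, presenceCutoff = 0) {
  if (!is.numeric(minFraction) || length(minFraction) != 1 ||
      minFraction <= 0 || minFraction > 1)
    .stopInvalid("minFraction must be in (0, 1]")
  prev <- colMeans(.denseData(exp) > presenceCutoff)
  keep <- which(prev >= minFraction)
  if (!length(keep)) warning("filterPrevalence kept 0 features")
  out <- .subsetAxis(exp, keep, "features")
  .recordOp(out, "filterPrevalence",
            list(minFraction = minFraction, presenceCutoff = presenceCutoff))
}
.registerOp("filterPrevalence", function(exp, params)
  suppressWarnings(filterPrevalence(exp, params$minFraction, params$presenceCutoff)))

#' Keep features with a non-missing value in a feature-metadata field
#'
#' E.g. keep only metabolites carrying a curated name or only features
#' with a taxonomy assignment.
#'
#' @param exp a FeatureExperiment.
#' @param field feature-metadata column name.
#' @return the filtered experiment.
#' @export
filterFeatureFieldPresent <- function(exp, field) {
  md <- featureData(exp)
  if (!field %in% names(md))
    .stopInvalid("field '%s' not found in feature metadata; available: %s",
                 field, paste(names(md), collapse = ", "))
  v <- md[[field]]
  keep <- which(!is.na(v) & !(is.character(v) & v == ""))
  if (!length(keep)) warning("filterFeatureFieldPresent kept 0 features")
  out <- .subsetAxis(exp, keep, "features")
  .recordOp(out, "filterFeatureFieldPresent", list(field = field))
}
.registerOp("filterFeatureFieldPresent", function(exp, params)
  suppressWarnings(filterFeatureFieldPresent(exp, params$field)))
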