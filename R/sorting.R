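#' Sort an axis by one or more metadata fields
#'
#' Stable lexicographic sort by the listed fields (first field is the
#' primary key). Stability means sorting an already-grouped experiment
#' by a further field preserves the outer grouping, so nested orderings
#' can be built incrementally. A field whose non-missing values all
#' parse as numbers is compared numerically.
#'
#' @param exp a FeatureExperiment.
#' @param axis "samples" or "features".
#' @param fields ordered character vector of metadata columns.
#' @return the sorted experiment.
#' @export
sortByMetadata <- function(exp, axis = c("samples", "features"), fields) {
  axis <- match.arg(axis)
  md <- if (axis == "samples") sampleData(exp) else featureData(exp)
  missing <- setdiff(fields, names(md))
  if (length(missing))
    .stopInvalid("field(s) %s not found on axis '%s'; available: %s",
                 paste(missing, collapse = ", "), axis,
                 paste(names(md), collapse = ", "))
  keys <- lapply(fields, function(f) .sortKey(md[[f]]))
  ord <- do.call(order, c(keys, list(method = "radix")))
  out <- .subsetAxis(exp, ord, axis)
  .recordOp(out, "sortByMetadata", list(axis = axis, fields = fields))
}
.registerOp("sortByMetadata", function(exp, params)
  sortByMetadata(exp, params$axis, unlist(params$fields)))

#' Sort an axis by total abundance or prevalence
#'
#' Ascending, ties keep the original order (stable).
#'
#' @param exp a FeatureExperiment.
#' @param axis "samples" or "features".
#' @param key "total" (sum of values along the other axis) or
#'   "prevalence" (fraction of nonzero values along the other axis).
#' @return the sorted experiment.
#' @export
sortByAbundance <- function(exp, axis = c("features", "samples"),
                            key = c("total", "prevalence")) {
  axis <- match.arg(axis)
  key <- match.arg(key)
  m <- .denseData(exp)
  v <- switch(paste(axis, key),
    "features total" = colSums(m),
    "features prevalence" = colMeans(m > 0),
    "samples total" = rowSums(m),
    "samples prevalence" = rowMeans(m > 0))
  ord <- order(v, method = "radix")
  out <- .subsetAxis(exp, ord, axis)
  .recordOp(out, "sortByAbundance", list(axis = axis, key = key))
}
.registerOp("sortByAbundance", function(exp, params)
  sortByAbundance(exp, params$axis, params$key))

#' Sort features by their center of mass across a fixed sample set
#'
#' For feature f over subset positions p = 0, 1, ..., k-1 (0-based
#' positions within the subset, not global sample indices),
#' \code{com(f) = sum(p * x) / sum(x)}. Features are ordered ascending
#' by com; features with zero total over the subset have no center of
#' mass and are placed last, with a warning. Useful for ordering
#' features along a time course or gradient defined by the subset.
#'
#' @param exp a FeatureExperiment.
#' @param sampleSubset integer vector of 1-based sample indices defining
#'   the gradient (default: all samples in current order).
#' @return the sorted experiment.
#' @export
sortCenterOfMass <- function(exp, sampleSubset = NULL) {
  if (is.null(sampleSubset)) sampleSubset <- seq_len(nSamples(exp))
  sampleSubset <- as.integer(sampleSubset)
  if (!length(sampleSubset))
    .stopInvalid("sampleSubset must be non-empty")
  if (min(sampleSubset) < 1 || max(sampleSubset) > nSamples(exp))
    .stopInvalid("sampleSubset out of range 1..%d", nSamples(exp))
  m <- .denseData(exp)[sampleSubset, , drop = FALSE]
  pos <- seq_len(nrow(m)) - 1
  tot <- colSums(m)
  com <- colSums(pos * m) / tot
  if (any(tot == 0)) {
    warning(sprintf("%d feature(s) with zero total over the subset placed last",
                    sum(tot == 0)))
    com[tot == 0] <- Inf
  }
  ord <- order(com, method = "radix")
  out <- .subsetAxis(exp, ord, "features")
  .recordOp(out, "sortCenterOfMass", list(sampleSubset = sampleSubset))
}
.registerOp("sortCenterOfMass", function(exp, params)
  suppressWarnings(sortCenterOfMass(exp, unlist(params$sampleSubset))))

# Deterministic leaf traversal of an hclust merge tree: at every merge,
# the subtree containing the lexicographically smallest item identifier
# is visited first. Keying the rule on identifiers rather than input
# positions fixes the left/right ambiguity of dendrograms AND makes the
# resulting order invariant to the input column order (identical trees
# traverse identically whatever the storage order).
.leafOrder <- function(hc, labels = NULL) {
  n <- length(hc$order)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  leaves <- vector("list", nrow(hc$merge))
  minLab <- function(x) min(labels[x])
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    la <- if (a < 0) -a else leaves[[a]]
    lb <- if (b < 0) -b else leaves[[b]]
    leaves[[i]] <- if (minLab(la) <= minLab(lb)) c(la, lb) else c(lb, la)
  }
  if (nrow(hc$merge) == 0) seq_len(n) else leaves[[nrow(hc$merge)]]
}

#' Order an axis by hierarchical clustering
#'
#' Default pipeline: log transform (base 2, cutoff 1), center and scale
#' to unit variance along the clustered axis (per feature when
#' clustering features, per sample when clustering samples), Euclidean
#' pairwise distances, single-linkage agglomerative clustering, then
#' reorder by a deterministic dendrogram leaf traversal (at each merge
#' the subtree containing the lowest original index comes first). Only
#' the order changes; the data values are untouched.
#'
#' @param exp a FeatureExperiment (>= 2 items on the chosen axis).
#' @param axis "features" (default) or "samples".
#' @param transform apply the log + unit-scaling preprocessing before
#'   computing distances (set FALSE to cluster raw values).
#' @param linkage "single" (default), "average" or "complete".
#' @return the reordered experiment.
#' @export
clusterOrder <- function(exp, axis = c("features", "samples"),
                         transform = TRUE,
                         linkage = c("single", "average", "complete")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  n <- if (axis == "features") nFeatures(exp) else nSamples(exp)
  if (n < 2)
    .stopInvalid("clusterOrder needs at least 2 %s", axis)
  m <- .denseData(exp)
  if (transform) {
    m <- log(pmax(m, 1), base = 2)
    m <- .scaleUnit(m, margin = if (axis == "features") 2 else 1)
  }
  pts <- if (axis == "features") t(m) else m
  rownames(pts) <- if (axis == "features") featureIds(exp) else sampleIds(exp)
  hc <- stats::hclust(stats::dist(pts), method = linkage)
  ord <- .leafOrder(hc, labels = rownames(pts))
  out <- .subsetAxis(exp, ord, axis)
  .recordOp(out, "clusterOrder",
            list(axis = axis, transform = transform, linkage = linkage))
}
.registerOp("clusterOrder", function(exp, params)
  clusterOrder(exp, params$axis, isTRUE(params$transform), params$linkage))
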