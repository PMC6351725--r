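# Local annotation store with curated-database semantics: typed
# ontology-term observations attached to feature identifiers, plus a
# rank-based term-enrichment test between two feature groups.

# score contributed by one annotation of a given type to each of its terms
.typeScores <- c(higher_in = 2, high_freq = 2, common = 1, lower_in = -2,
                 contamination = 0, other = 0)

.newStore <- function(annotations) {
  names(annotations) <- vapply(annotations, `[[`, "", "annotation_id")
  index <- list()
  for (a in annotations)
    for (f in a$features)
      index[[f]] <- c(index[[f]], a$annotation_id)
  methods::new("AnnotationStore", annotations = annotations, index = index)
}

.annotationRecord <- function(annotation_id, type, terms, features,
                              experiment = "") {
  list(annotation_id = as.character(annotation_id), type = type,
       terms = as.character(terms), experiment = as.character(experiment),
       features = as.character(features))
}

#' Load an annotation store from disk
#'
#' Two on-disk formats are accepted: JSON lines (one JSON object per
#' line with fields \code{annotation_id}, \code{type}, \code{terms},
#' \code{experiment}, \code{features}) and tab-delimited text with the
#' same column names, \code{terms} and \code{features} being
#' semicolon-separated within their cell. The format is sniffed from
#' the first non-empty character (\code{\{} means JSON lines) and can be
#' forced with \code{format}.
#'
#' @param path file path.
#' @param format "auto", "jsonl" or "tsv".
#' @return a validated \code{\linkS4class{AnnotationStore}}.
#' @export
loadStore <- function(path, format = c("auto", "jsonl", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopInvalid("annotation file '%s' not found", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(.newStore(list()))
  if (format == "auto")
    format <- if (startsWith(trimws(lines[1]), "{")) "jsonl" else "tsv"
  if (format == "jsonl") {
    ann <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e)
                        .stopInvalid("malformed JSON in record %d: %s",
                                     i, conditionMessage(e)))
      .annotationRecord(rec$annotation_id, rec$type, rec$terms,
                        rec$features,
                        if (is.null(rec$experiment)) "" else rec$experiment)
    })
  } else {
    df <- utils::read.delim(text = lines, sep = "\t", header = TRUE,
                            colClasses = "character", check.names = FALSE)
    need <- c("annotation_id", "type", "terms", "features")
    if (!all(need %in% names(df)))
      .stopInvalid("tsv store must have columns: %s", paste(need, collapse = ", "))
    ann <- lapply(seq_len(nrow(df)), function(i) {
      .annotationRecord(df$annotation_id[i], df$type[i],
                        strsplit(df$terms[i], ";", fixed = TRUE)[[1]],
                        strsplit(df$features[i], ";", fixed = TRUE)[[1]],
                        if ("experiment" %in% names(df)) df$experiment[i] else "")
    })
  }
  ids <- vapply(ann, `[[`, "", "annotation_id")
  if (anyDuplicated(ids))
    .stopInvalid("duplicated annotation id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  store <- .newStore(ann)
  methods::validObject(store)
  store
}

#' Save an annotation store as JSON lines
#'
#' @param store an AnnotationStore.
#' @param path destination path.
#' @return invisibly, the path. \code{loadStore(saveStore(s, p))}
#'   reproduces the store.
#' @export
saveStore <- function(store, path) {
  lines <- vapply(store@annotations, function(a)
    as.character(jsonlite::toJSON(a, auto_unbox = TRUE)), "")
  writeLines(unname(lines), path)
  invisible(path)
}

#' Annotations covering a feature
#'
#' @param store an AnnotationStore.
#' @param featureId feature identifier.
#' @return list of annotation records whose feature set contains the id
#'   (empty list for unannotated features).
#' @export
featureAnnotations <- function(store, featureId) {
  ids <- store@index[[featureId]]
  if (is.null(ids)) list() else unname(store@annotations[ids])
}

#' Term-by-feature score matrix
#'
#' For every ontology term and feature, sums the contributions of the
#' annotations containing both: +2 for "higher_in" or "high_freq", +1
#' for "common", -2 for "lower_in", 0 for "contamination"/"other".
#' Features with no annotations get all-zero columns — the absence of a
#' term is informative in the downstream rank test.
#'
#' @param store an AnnotationStore.
#' @param featureIds character vector of features (matrix columns, in
#'   this order).
#' @return numeric matrix terms x features with dimnames; 0 rows when
#'   no annotation touches the features.
#' @export
termScoreMatrix <- function(store, featureIds) {
  featureIds <- as.character(featureIds)
  annIds <- unique(unlist(store@index[featureIds], use.names = FALSE))
  terms <- sort(unique(unlist(lapply(store@annotations[annIds], `[[`, "terms"),
                              use.names = FALSE)))
  m <- matrix(0, length(terms), length(featureIds),
              dimnames = list(terms, featureIds))
  for (a in store@annotations[annIds]) {
    w <- .typeScores[[a$type]]
    if (w == 0 || !length(a$terms)) next
    cols <- intersect(a$features, featureIds)
    if (!length(cols)) next
    m[a$terms, cols] <- m[a$terms, cols, drop = FALSE] + w
  }
  m
}

#' Term-enrichment test between two feature groups
#'
#' Builds the term score matrix over the union of the two groups, ranks
#' each term's scores across features (mid-ranks), takes the
#' mean-rank difference between the groups as the per-term statistic,
#' builds the null by permuting the group labels of the \emph{features},
#' and controls the FDR with dsFDR at \code{alpha}. A term is reported
#' as enriched in the group where its mean score is larger.
#'
#' @param store an AnnotationStore.
#' @param group1Ids,group2Ids disjoint, non-empty feature id sets
#'   (e.g. features higher in one sample group vs the rest).
#' @param nPermutations number of label permutations.
#' @param alpha target FDR level.
#' @param seed integer seed.
#' @return data.frame with one row per term: term, stat (mean rank
#'   group1 - group2), p, q, rejected, enrichedGroup ("group1"/"group2"),
#'   meanScore1, meanScore2. Empty when no annotation touches the
#'   features.
#' @export
enrichTerms <- function(store, group1Ids, group2Ids, nPermutations = 1000,
                        alpha = 0.1, seed = NULL) {
  group1Ids <- as.character(group1Ids)
  group2Ids <- as.character(group2Ids)
  if (length(intersect(group1Ids, group2Ids)))
    .stopInvalid("feature groups overlap")
  if (!length(group1Ids) || !length(group2Ids))
    .stopInvalid("both feature groups must be non-empty")
  allIds <- c(group1Ids, group2Ids)
  scores <- termScoreMatrix(store, allIds)
  empty <- data.frame(term = character(0), stat = numeric(0),
                      p = numeric(0), q = numeric(0),
                      rejected = logical(0), enrichedGroup = character(0),
                      meanScore1 = numeric(0), meanScore2 = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(scores) == 0) return(empty)
  labels <- c(rep(TRUE, length(group1Ids)), rep(FALSE, length(group2Ids)))
  x <- t(scores)                       # features x terms
  xr <- perFeatureTransform(x, "rank") # rank scores across features, per term
  sObs <- meandiffStat(xr, labels)
  null <- permutationNull(xr, labels, nPermutations = nPermutations,
                          seed = seed)
  p <- permutationPvalues(sObs, null$stats, twoSided = TRUE,
                          exhaustive = FALSE)
  ctl <- dsfdrControl(sObs, null$stats, alpha)
  data.frame(term = rownames(scores),
             stat = unname(sObs),
             p = unname(p),
             q = unname(ctl$qValues),
             rejected = unname(ctl$rejected),
             enrichedGroup = unname(ifelse(sObs > 0, "group1", "group2")),
             meanScore1 = unname(rowMeans(scores[, labels, drop = FALSE])),
             meanScore2 = unname(rowMeans(scores[, !labels, drop = FALSE])),
             stringsAsFactors = FALSE)
}

#' Flag known contaminants among an experiment's features
#'
#' Writes a feature-metadata column \code{annotationStatus} with value
#' "contaminant" for features covered by any contamination-type
#' annotation, "annotated" for features with any other annotation, and
#' "none" otherwise. The column is usable by
#' \code{\link{filterByMetadata}} and as a heatmap feature color bar.
#'
#' @param store an AnnotationStore.
#' @param exp a FeatureExperiment.
#' @return the experiment with the new/updated column.
#' @export
flagContaminants <- function(store, exp) {
  status <- vapply(featureIds(exp), function(f) {
    anns <- featureAnnotations(store, f)
    if (!length(anns)) return("none")
    types <- vapply(anns, `[[`, "", "type")
    if (any(types == "contamination")) "contaminant" else "annotated"
  }, "")
  md <- featureData(exp)
  md$annotationStatus <- unname(status)
  featureData(exp) <- md
  recordHistory(exp, "flagContaminants", list(column = "annotationStatus"))
}

#' Most common annotation term for a feature among candidates
#'
#' Sums the per-annotation scores (+2 higher_in/high_freq, +1 common,
#' -2 lower_in) of each candidate term over the feature's annotations
#' and returns the candidate with the largest positive total. If no
#' candidate scores above zero (including unannotated features), the
#' bucket label "other" is returned. Ties go to the earlier candidate
#' in the given order.
#'
#' @param store an AnnotationStore.
#' @param featureId feature identifier.
#' @param candidateTerms non-empty character vector, in priority order.
#' @return one of \code{candidateTerms} or "other".
#' @export
mostCommonTerm <- function(store, featureId, candidateTerms) {
  if (!length(candidateTerms)) .stopInvalid("candidateTerms must be non-empty")
  totals <- stats::setNames(numeric(length(candidateTerms)), candidateTerms)
  for (a in featureAnnotations(store, featureId)) {
    w <- .typeScores[[a$type]]
    hit <- intersect(candidateTerms, a$terms)
    totals[hit] <- totals[hit] + w
  }
  if (max(totals) <= 0) return("other")
  candidateTerms[which.max(totals)]
}
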