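# Readers and writers for the supported table dialects, and assembly of
# FeatureExperiment objects from a table plus metadata files.
#
# On-disk orientation is normalized on read: whatever the file stores,
# the in-memory matrix is always samples x features.

.sniffDialect <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (length(first) && startsWith(trimws(first), "{")) return("biom_json")
  if (grepl("\\.(csv|ms1)$", path, ignore.case = TRUE)) return("ms1_bucket")
  "tsv"
}

.checkIdsValues <- function(m, path, allowNegative = FALSE) {
  if (anyDuplicated(rownames(m)))
    .stopInvalid("duplicated sample id(s) in '%s': %s", path,
                 paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    .stopInvalid("duplicated feature id(s) in '%s': %s", path,
                 paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (anyNA(m))
    .stopInvalid("non-numeric or missing value(s) in table '%s'", path)
  if (!allowNegative && length(m) && min(m) < 0)
    .stopInvalid("negative value(s) in table '%s'", path)
  m
}

.readDelimTable <- function(path, sep) {
  df <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                          row.names = NULL, colClasses = "character")
  if (ncol(df) < 2)
    .stopInvalid("table '%s' needs an id column plus at least one data column", path)
  ids <- df[[1]]
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(df),
                                       dimnames = list(NULL, names(df)[-1]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    .stopInvalid("non-numeric value in '%s' at data row %d, column '%s'",
                 path, bad[1], colnames(vals)[bad[2]])
  }
  rownames(vals) <- ids
  vals
}

#' Read an abundance table
#'
#' Supported dialects: BIOM-JSON (format 1.0, read via the biomformat
#' package), tab-delimited text, and metabolomics MS1 bucket tables
#' (comma- or tab-delimited, feature ids of the form
#' \code{"<mz>_<rt>"}, parsed into feature-metadata columns MZ and RT).
#' The dialect is sniffed from the file and can be forced.
#'
#' @param path file path.
#' @param dialect "auto", "biom_json", "tsv" or "ms1_bucket".
#' @param featuresAsRows for text dialects: the on-disk orientation
#'   (default TRUE, the common classic export: first column feature id,
#'   header row sample ids). Ignored for BIOM, which is
#'   observation-major by definition.
#' @param allowNegative accept negative values (transformed, non-count
#'   tables); count tables must be non-negative.
#' @return list with \code{data} (samples x features matrix),
#'   \code{sampleIds}, \code{featureIds} and \code{featureMetadata}
#'   (data.frame; MZ/RT columns for MS1 tables, otherwise empty).
#' @export
readTable <- function(path, dialect = c("auto", "biom_json", "tsv", "ms1_bucket"),
                      featuresAsRows = TRUE, allowNegative = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopInvalid("table file '%s' not found", path)
  if (dialect == "auto") dialect <- .sniffDialect(path)
  featureMd <- NULL
  if (dialect == "biom_json") {
    b <- tryCatch(biomformat::read_biom(path),
                  error = function(e)
                    .stopInvalid("failed to parse BIOM file '%s': %s",
                                 path, conditionMessage(e)))
    m <- t(as(biomformat::biom_data(b), "matrix"))  # obs-major -> samples x features
  } else if (dialect == "ms1_bucket") {
    first <- readLines(path, n = 1, warn = FALSE)
    sep <- if (lengths(regmatches(first, gregexpr(",", first))) >
               lengths(regmatches(first, gregexpr("\t", first)))) "," else "\t"
    raw <- .readDelimTable(path, sep)
    if (!featuresAsRows) raw <- t(raw)
    m <- t(raw)
    mz <- suppressWarnings(as.numeric(sub("^([^_]+)_.*$", "\\1", colnames(m))))
    rt <- suppressWarnings(as.numeric(sub("^[^_]+_(.*)$", "\\1", colnames(m))))
    bad <- is.na(mz) | is.na(rt)
    if (any(bad))
      warning(sprintf("%d feature id(s) not of the form <mz>_<rt>; MZ/RT set missing",
                      sum(bad)))
    featureMd <- data.frame(MZ = mz, RT = rt, row.names = colnames(m))
  } else {
    raw <- .readDelimTable(path, "\t")
    m <- if (featuresAsRows) t(raw) else raw
  }
  m <- .checkIdsValues(m, path, allowNegative)
  if (is.null(featureMd))
    featureMd <- data.frame(row.names = colnames(m))
  list(data = m, sampleIds = rownames(m), featureIds = colnames(m),
       featureMetadata = featureMd)
}

#' Read a tab-delimited metadata file
#'
#' Expects a header row; the identifier column defaults to the first
#' column. Empty cells and "NA" become the missing marker \code{NA}.
#' Columns whose non-missing values all parse as numbers are stored
#' numeric, otherwise as character. CRLF and LF files parse
#' identically.
#'
#' @param path file path.
#' @param idColumn identifier column name (default: first column).
#' @return data.frame keyed by identifier (row names); the id column is
#'   retained as a regular column too.
#' @export
readMetadata <- function(path, idColumn = NULL) {
  if (!file.exists(path)) .stopInvalid("metadata file '%s' not found", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("", "NA"), quote = "")
  if (is.null(idColumn)) idColumn <- names(df)[1]
  if (!idColumn %in% names(df))
    .stopInvalid("id column '%s' not found in '%s'", idColumn, path)
  ids <- df[[idColumn]]
  if (anyDuplicated(ids))
    .stopInvalid("duplicated identifier(s) in '%s': %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rownames(df) <- ids
  .coerceColumns(df)
}

#' Assemble a FeatureExperiment from a table and metadata
#'
#' Joins the abundance table with the metadata tables by identifier.
#' Table samples (features) without a metadata row are kept, with
#' missing metadata and a warning — silently dropping them would change
#' downstream statistics; metadata rows absent from the table are
#' dropped with a message. Zero overlap between table sample ids and
#' metadata ids raises an error (almost always a wrong key column).
#' If \code{normalizeTotal} is given, total-sum scaling is applied; if
#' \code{minFeatureTotal} is given, features whose total (after the
#' normalization, when both are requested) is below it are dropped.
#'
#' @param table result of \code{\link{readTable}} (or a compatible list).
#' @param sampleMd,featureMd metadata data.frames keyed by id (e.g.
#'   from \code{\link{readMetadata}}), or NULL.
#' @param experimentType "generic", "amplicon" or "ms1".
#' @param normalizeTotal optional per-sample total for TSS.
#' @param minFeatureTotal optional minimum per-feature total; strictly
#'   smaller totals are filtered away (applied after normalization).
#' @param sparse storage hint.
#' @return a FeatureExperiment.
#' @export
assembleExperiment <- function(table, sampleMd = NULL, featureMd = NULL,
                               experimentType = c("generic", "amplicon", "ms1"),
                               normalizeTotal = NULL, minFeatureTotal = NULL,
                               sparse = FALSE) {
  experimentType <- match.arg(experimentType)
  m <- table$data
  alignMd <- function(md, ids, what) {
    if (is.null(md)) return(NULL)
    common <- intersect(rownames(md), ids)
    if (!length(common))
      .stopInvalid("no overlap between table %s ids and metadata ids (wrong key column?)",
                   what)
    dropped <- setdiff(rownames(md), ids)
    if (length(dropped))
      message(sprintf("dropping %d %s metadata row(s) absent from the table",
                      length(dropped), what))
    absent <- setdiff(ids, rownames(md))
    if (length(absent))
      warning(sprintf("%d table %s(s) have no metadata row; kept with missing metadata",
                      length(absent), what))
    md[ids, , drop = FALSE]   # NA-filled rows for absent ids
  }
  smd <- alignMd(sampleMd, rownames(m), "sample")
  fmd0 <- table$featureMetadata
  fmd <- alignMd(featureMd, colnames(m), "feature")
  if (!is.null(fmd) && !is.null(fmd0) && ncol(fmd0))
    fmd <- cbind(fmd0, fmd[colnames(m), setdiff(names(fmd), names(fmd0)),
                           drop = FALSE])
  else if (is.null(fmd)) fmd <- fmd0
  if (!is.null(smd)) rownames(smd) <- rownames(m)
  if (!is.null(fmd)) rownames(fmd) <- colnames(m)
  exp <- featureExperiment(m, sampleMetadata = smd, featureMetadata = fmd,
                           sparse = sparse, experimentType = experimentType)
  if (!is.null(normalizeTotal)) exp <- normalizeTSS(exp, normalizeTotal)
  if (!is.null(minFeatureTotal)) exp <- filterSumAbundance(exp, minFeatureTotal)
  exp
}

#' Write an experiment bundle to disk
#'
#' Writes the abundance table (\code{<prefix>_table.tsv} /
#' \code{.biom} / \code{.csv} depending on dialect), both metadata
#' tables (\code{<prefix>_samples.tsv}, \code{<prefix>_features.tsv})
#' and the operation history (\code{<prefix>_history.json}).
#' \code{\link{readExperiment}} on the same prefix reproduces the
#' matrix and metadata.
#'
#' @param exp a FeatureExperiment.
#' @param outPrefix path prefix for the output files.
#' @param dialect "tsv" (default), "biom_json" or "ms1_bucket".
#' @return invisibly, the named vector of written paths.
#' @export
writeExperiment <- function(exp, outPrefix,
                            dialect = c("tsv", "biom_json", "ms1_bucket")) {
  dialect <- match.arg(dialect)
  m <- .denseData(exp)
  paths <- c()
  if (dialect == "biom_json") {
    tablePath <- paste0(outPrefix, "_table.biom")
    b <- biomformat::make_biom(t(m))    # observation-major on disk
    biomformat::write_biom(b, tablePath)
  } else {
    sep <- if (dialect == "ms1_bucket") "," else "\t"
    tablePath <- paste0(outPrefix,
                        if (dialect == "ms1_bucket") "_table.csv" else "_table.tsv")
    fm <- t(m)
    chr <- matrix(sprintf("%.17g", fm), nrow(fm), ncol(fm),
                  dimnames = dimnames(fm))   # exact double round-trip
    df <- data.frame(featureId = rownames(chr), chr, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- "featureId"
    utils::write.table(df, tablePath, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  paths["table"] <- tablePath
  writeMd <- function(md, ids, path, idName) {
    out <- cbind(stats::setNames(data.frame(ids, stringsAsFactors = FALSE), idName),
                 md[, setdiff(names(md), idName), drop = FALSE])
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    path
  }
  paths["samples"] <- writeMd(sampleData(exp), sampleIds(exp),
                              paste0(outPrefix, "_samples.tsv"), "sampleId")
  paths["features"] <- writeMd(featureData(exp), featureIds(exp),
                               paste0(outPrefix, "_features.tsv"), "featureId")
  histPath <- paste0(outPrefix, "_history.json")
  jsonlite::write_json(opHistory(exp), histPath, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  paths["history"] <- histPath
  meta <- list(experimentType = experimentType(exp),
               sparse = exp@sparse, nonCount = exp@nonCount,
               normalizedTotal = if (length(normalizedTotal(exp)))
                 normalizedTotal(exp) else NULL,
               dialect = dialect)
  metaPath <- paste0(outPrefix, "_experiment.json")
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths["meta"] <- metaPath
  invisible(paths)
}

#' Read an experiment bundle written by writeExperiment
#'
#' @param outPrefix the prefix the bundle was written with.
#' @return a FeatureExperiment with the stored history attached.
#' @export
readExperiment <- function(outPrefix) {
  metaPath <- paste0(outPrefix, "_experiment.json")
  if (!file.exists(metaPath))
    .stopInvalid("no experiment bundle at prefix '%s'", outPrefix)
  meta <- jsonlite::fromJSON(metaPath)
  tablePath <- paste0(outPrefix,
                      switch(meta$dialect, biom_json = "_table.biom",
                             ms1_bucket = "_table.csv", "_table.tsv"))
  tab <- readTable(tablePath, dialect = meta$dialect,
                   allowNegative = isTRUE(meta$nonCount))
  smd <- readMetadata(paste0(outPrefix, "_samples.tsv"))
  fmd <- readMetadata(paste0(outPrefix, "_features.tsv"))
  exp <- methods::new("FeatureExperiment",
    data = if (isTRUE(meta$sparse)) Matrix::Matrix(tab$data, sparse = TRUE)
           else tab$data,
    sampleMetadata = smd[tab$sampleIds, , drop = FALSE],
    featureMetadata = fmd[tab$featureIds, , drop = FALSE],
    sparse = isTRUE(meta$sparse),
    nonCount = isTRUE(meta$nonCount),
    experimentType = meta$experimentType)
  if (!is.null(meta$normalizedTotal))
    exp@normalizedTotal <- meta$normalizedTotal
  hist <- jsonlite::fromJSON(paste0(outPrefix, "_history.json"),
                             simplifyVector = FALSE)
  exp@history <- hist
  methods::validObject(exp)
  exp
}
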