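# Deterministic synthetic-data generators. These emulate sparse,
# overdispersed amplicon-style count tables with a known planted truth,
# so every statistical claim in the package can be tested without any
# external download.

.randomSeq <- function(n, len = 20) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
}

#' Generate a two-group count experiment with planted effects
#'
#' Per-feature baseline means are drawn log-normal (sdlog 1), giving the
#' orders-of-magnitude abundance spread typical of amplicon data. The
#' first \code{nDiff} features have their group-1 mean multiplied by
#' \code{effectFold}. Counts are negative-binomial with variance
#' \code{mu + dispersion * mu^2} (dispersion 0.2 by default, moderate
#' overdispersion); per-sample sequencing depth is uniform in
#' \code{depth} +/- 20 percent, and expected counts are the
#' depth-scaled baseline weights; the fold change multiplies the
#' planted features' group-1 means directly, leaving all null features
#' with identical means in both groups so the returned truth mask is
#' exact. Sample metadata
#' carries the group, a random two-level extraction plate, and a
#' continuous covariate correlated (rho = 0.8) with the first planted
#' feature for correlation tests. Feature ids are random nucleotide
#' 20-mers; the experiment type is "amplicon".
#'
#' @param nPerGroup integer pair: samples in group 1 and group 2.
#' @param nFeatures number of features.
#' @param nDiff number of planted differential features (the first
#'   \code{nDiff}); must not exceed \code{nFeatures}.
#' @param effectFold group-1 mean multiplier (>= 1); 1 plants nothing
#'   and the truth mask is all-FALSE.
#' @param depth nominal per-sample read depth.
#' @param dispersion negative-binomial dispersion (variance
#'   \code{mu + dispersion * mu^2}); 0 gives Poisson counts.
#' @param seed integer seed; the same seed reproduces the experiment
#'   exactly.
#' @return list with \code{experiment} (a FeatureExperiment) and
#'   \code{truth} (logical vector, TRUE for planted features).
#' @export
makeCountExperiment <- function(nPerGroup = c(10, 10), nFeatures = 100,
                                nDiff = 10, effectFold = 4, depth = 10000,
                                dispersion = 0.2, seed = NULL) {
  if (length(nPerGroup) != 2 || any(nPerGroup < 2))
    .stopInvalid("nPerGroup must be two group sizes >= 2")
  if (nDiff > nFeatures) .stopInvalid("nDiff must not exceed nFeatures")
  if (effectFold < 1) .stopInvalid("effectFold must be >= 1")
  if (dispersion < 0) .stopInvalid("dispersion must be >= 0")
  .withSeed(seed, {
    n <- sum(nPerGroup)
    group <- rep(c("g1", "g2"), nPerGroup)
    baseline <- stats::rlnorm(nFeatures, meanlog = 0, sdlog = 1)
    w1 <- baseline
    if (nDiff > 0 && effectFold > 1)
      w1[seq_len(nDiff)] <- w1[seq_len(nDiff)] * effectFold
    depths <- stats::runif(n, 0.8 * depth, 1.2 * depth)
    # expected counts: depth-scaled baseline weights; the planted
    # features' group-1 means are multiplied directly, leaving every
    # null feature's mean untouched in both groups (so the truth mask
    # is exact; no compositional coupling is introduced)
    p1 <- w1 / sum(baseline)
    p2 <- baseline / sum(baseline)
    mu <- outer(depths, rep(1, nFeatures)) *
      rbind(matrix(p1, nPerGroup[1], nFeatures, byrow = TRUE),
            matrix(p2, nPerGroup[2], nFeatures, byrow = TRUE))
    counts <- if (dispersion > 0)
      matrix(stats::rnbinom(n * nFeatures, mu = mu, size = 1 / dispersion),
             n, nFeatures)
    else
      matrix(stats::rpois(n * nFeatures, lambda = mu), n, nFeatures)
    plate <- sample(c("pa", "pb"), n, replace = TRUE)
    z <- as.vector(scale(counts[, 1]))
    if (anyNA(z)) z <- rep(0, n)       # degenerate all-equal first feature
    covariate <- 0.8 * z + sqrt(1 - 0.8^2) * stats::rnorm(n)
    smd <- data.frame(group = group, plate = plate, covariate = covariate,
                      row.names = sprintf("S%03d", seq_len(n)),
                      stringsAsFactors = FALSE)
    rownames(counts) <- rownames(smd)
    colnames(counts) <- .randomSeq(nFeatures)
    truth <- c(rep(effectFold > 1, nDiff), rep(FALSE, nFeatures - nDiff))
    fe <- featureExperiment(counts, sampleMetadata = smd,
                            experimentType = "amplicon")
    list(experiment = fe, truth = truth)
  })
}

#' Generate an annotation store with planted and decoy annotations
#'
#' The planted annotation (if given) ties one term to a chosen feature
#' subset with a chosen annotation type. Decoy annotations draw a
#' random term from a pool of \code{nTerms} decoy terms and a random
#' feature subset, with a random non-contamination type — so decoy
#' term/feature associations are exchangeable across any feature
#' grouping.
#'
#' @param featureIds feature identifiers the store covers.
#' @param nTerms size of the decoy term pool.
#' @param planted NULL or list(term =, features =, type =) for the
#'   planted annotation; \code{features} must be a subset of
#'   \code{featureIds}.
#' @param nDecoyAnnotations number of decoy annotations.
#' @param seed integer seed.
#' @return an \code{\linkS4class{AnnotationStore}}.
#' @export
makeAnnotationStore <- function(featureIds, nTerms = 200, planted = NULL,
                                nDecoyAnnotations = 200, seed = NULL) {
  featureIds <- as.character(featureIds)
  if (!is.null(planted) && length(setdiff(planted$features, featureIds)))
    .stopInvalid("planted features must be a subset of featureIds")
  .withSeed(seed, {
    ann <- list()
    if (!is.null(planted))
      ann[[length(ann) + 1]] <- .annotationRecord(
        "planted1", planted$type, planted$term, planted$features, "planted")
    decoyTerms <- sprintf("decoy_term_%03d", seq_len(nTerms))
    types <- c("higher_in", "lower_in", "common", "high_freq")
    for (i in seq_len(nDecoyAnnotations)) {
      sz <- max(1, stats::rbinom(1, length(featureIds), 0.2))
      ann[[length(ann) + 1]] <- .annotationRecord(
        sprintf("decoy%04d", i), sample(types, 1), sample(decoyTerms, 1),
        sample(featureIds, sz), "decoy")
    }
    store <- .newStore(ann)
    methods::validObject(store)
    store
  })
}
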