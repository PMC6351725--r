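#' Total-sum-scaling normalization
#'
#' Rescales every sample so its values sum to \code{total} (default
#' 10000), turning counts into fixed-total relative abundances. Within-
#' sample proportions are conserved.
#'
#' @param exp a FeatureExperiment with non-negative values.
#' @param total positive per-sample total after scaling.
#' @param dropZero drop all-zero samples (with a warning) instead of
#'   raising an error.
#' @return the normalized experiment; \code{normalizedTotal(exp)} is set.
#' @examples
#' fe <- featureExperiment(matrix(c(1, 3, 2, 2), 2, 2, byrow = TRUE))
#' abundance(normalizeTSS(fe, total = 10000))
#' @export
normalizeTSS <- function(exp, total = 10000, dropZero = FALSE) {
  if (!is.numeric(total) || length(total) != 1 || total <= 0)
    .stopInvalid("total must be a single positive number")
  m <- .denseData(exp)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    if (!dropZero)
      .stopInvalid("all-zero sample(s): %s (use dropZero = TRUE to drop)",
                   paste(rownames(m)[rs == 0], collapse = ", "))
    keep <- which(rs > 0)
    warning(sprintf("dropping %d all-zero sample(s)", sum(rs == 0)))
    exp <- .subsetAxis(exp, keep, "samples")
    m <- .denseData(exp)
    rs <- rs[keep]
  }
  exp <- .setData(exp, m * (total / rs))
  exp@normalizedTotal <- total
  .recordOp(exp, "normalizeTSS",
            list(total = total, dropZero = dropZero))
}
.registerOp("normalizeTSS", function(exp, params)
  normalizeTSS(exp, params$total, isTRUE(params$dropZero)))

#' Total-sum scaling with iterative removal of dominant outliers
#'
#' Per sample, features whose within-sample relative abundance exceeds
#' \code{outlierFraction} are excluded from the scaling denominator; the
#' relative abundances of the remaining features are recomputed and the
#' exclusion repeated until the excluded set is stable (it can only
#' grow, so the iteration terminates). The final scaling factor
#' \code{total / sum(non-excluded)} is applied to \emph{all} features of
#' the sample, excluded ones included; excluded feature ids are
#' reported via \code{message()}. This keeps one dominant bloom from
#' compressing everything else in the sample.
#'
#' @inheritParams normalizeTSS
#' @param outlierFraction relative-abundance cutoff in (0, 1]; a
#'   feature strictly above it is excluded from the denominator. With
#'   \code{outlierFraction = 1} this reduces to \code{\link{normalizeTSS}}.
#' @return the normalized experiment.
#' @export
normalizeTSSOutliers <- function(exp, total = 10000, outlierFraction = 0.1) {
  if (!is.numeric(outlierFraction) || length(outlierFraction) != 1 ||
      outlierFraction <= 0 || outlierFraction > 1)
    .stopInvalid("outlierFraction must be in (0, 1]")
  if (!is.numeric(total) || length(total) != 1 || total <= 0)
    .stopInvalid("total must be a single positive number")
  m <- .denseData(exp)
  if (any(rowSums(m) == 0))
    .stopInvalid("all-zero sample(s): %s",
                 paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  out <- m
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    excluded <- rep(FALSE, length(x))
    repeat {
      s <- sum(x[!excluded])
      if (s == 0)
        .stopInvalid("all features excluded as outliers in sample '%s'",
                     rownames(m)[i])
      newExcluded <- excluded | (x / s > outlierFraction)
      if (identical(newExcluded, excluded)) break
      excluded <- newExcluded
    }
    if (any(excluded))
      message(sprintf("sample '%s': excluded from scaling denominator: %s",
                      rownames(m)[i],
                      paste(colnames(m)[excluded], collapse = ", ")))
    out[i, ] <- x * (total / sum(x[!excluded]))
  }
  exp <- .setData(exp, out)
  exp@normalizedTotal <- total
  .recordOp(exp, "normalizeTSSOutliers",
            list(total = total, outlierFraction = outlierFraction))
}
.registerOp("normalizeTSSOutliers", function(exp, params)
  suppressMessages(normalizeTSSOutliers(exp, params$total, params$outlierFraction)))

#' Centered log-ratio transform
#'
#' Per sample, \code{y = ln(x + c) - mean(ln(x + c))} with pseudocount
#' \code{c} handling zeros. Each transformed sample sums to zero; the
#' result may contain negative values and is flagged non-count.
#'
#' @inheritParams normalizeTSS
#' @param pseudocount positive shift added before the log.
#' @export
transformCLR <- function(exp, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    .stopInvalid("pseudocount must be a single positive number")
  m <- log(.denseData(exp) + pseudocount)
  m <- m - rowMeans(m)
  exp@nonCount <- TRUE
  exp@normalizedTotal <- numeric(0)
  exp <- .setData(exp, m)
  .recordOp(exp, "transformCLR", list(pseudocount = pseudocount))
}
.registerOp("transformCLR", function(exp, params)
  transformCLR(exp, params$pseudocount))

#' Log transform with a minimal read cutoff
#'
#' \code{y = log_base(max(x, minCutoff))}: the cutoff handles zeros, so
#' with the defaults (base 2, cutoff 1) zero counts map to 0. The
#' transform is monotone non-decreasing in x.
#'
#' @inheritParams normalizeTSS
#' @param base logarithm base (> 1).
#' @param minCutoff positive floor applied before the log.
#' @export
transformLog <- function(exp, base = 2, minCutoff = 1) {
  if (!is.numeric(minCutoff) || length(minCutoff) != 1 || minCutoff <= 0)
    .stopInvalid("minCutoff must be a single positive number")
  if (!is.numeric(base) || length(base) != 1 || base <= 1)
    .stopInvalid("base must be > 1")
  m <- log(pmax(.denseData(exp), minCutoff), base = base)
  exp@nonCount <- TRUE
  exp@normalizedTotal <- numeric(0)
  exp <- .setData(exp, m)
  .recordOp(exp, "transformLog", list(base = base, minCutoff = minCutoff))
}
.registerOp("transformLog", function(exp, params)
  transformLog(exp, params$base, params$minCutoff))

#' Binarize to presence/absence
#'
#' \code{y = 1} if \code{x > cutoff} else 0 (strict inequality, so at
#' the default cutoff 0 any positive count is "present"). Idempotent.
#'
#' @inheritParams normalizeTSS
#' @param cutoff presence threshold (>= 0).
#' @export
binarize <- function(exp, cutoff = 0) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0)
    .stopInvalid("cutoff must be a single non-negative number")
  m <- (.denseData(exp) > cutoff) * 1
  exp@normalizedTotal <- numeric(0)
  exp <- .setData(exp, m)
  .recordOp(exp, "binarize", list(cutoff = cutoff))
}
.registerOp("binarize", function(exp, params) binarize(exp, params$cutoff))

#' Per-feature centering and unit-variance scaling
#'
#' Returns the matrix (not an experiment) in which every feature column
#' has mean 0 and population (divide-by-n) standard deviation 1.
#' Zero-variance features map to all-zero columns. Used by
#' \code{\link{clusterOrder}} before computing distances.
#'
#' @param exp a FeatureExperiment.
#' @return a numeric samples x features matrix.
#' @export
scaleFeaturesUnit <- function(exp) {
  .scaleUnit(.denseData(exp), margin = 2)
}

# margin 2 = scale columns (features), margin 1 = scale rows (samples);
# population sd (n denominator).
.scaleUnit <- function(m, margin) {
  if (margin == 1) return(t(.scaleUnit(t(m), 2)))
  n <- nrow(m)
  mu <- colMeans(m)
  centered <- sweep(m, 2, mu)
  sd <- sqrt(colMeans(centered^2))
  sd[sd == 0] <- Inf            # constant columns -> zeros
  sweep(centered, 2, sd, "/")
}
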