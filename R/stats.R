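# Permutation-based nonparametric tests with discrete-FDR control.
#
# The differential-abundance test compares a per-feature statistic (mean
# difference after an optional rank or presence/absence transform)
# between two sample groups; significance comes from the permutation
# distribution of the statistic under random relabeling. Because the
# data are sparse and discrete, the attainable p-values are coarse;
# dsFDR therefore operates directly on the statistic scale rather than
# on p-values, estimating for every candidate threshold t the expected
# number of null features exceeding t from the permutations themselves.

.statTol <- 1e-9

#' Within-feature transform applied before the test statistic
#'
#' @param x numeric matrix (selected samples x features).
#' @param transform "rank" (mid-ranks within each feature across the
#'   selected samples; ties share their average rank), "binarize"
#'   (presence/absence: value > 0), or "none".
#' @return the transformed matrix.
#' @export
perFeatureTransform <- function(x, transform = c("rank", "none", "binarize")) {
  transform <- match.arg(transform)
  switch(transform,
    none = x,
    binarize = (x > 0) * 1,
    rank = {
      r <- apply(x, 2, rank)            # mid-ranks for ties
      if (!is.matrix(r)) r <- matrix(r, nrow = nrow(x))
      dimnames(r) <- dimnames(x)
      r
    })
}

#' Mean-difference statistic between two sample groups
#'
#' \code{stat_j = mean(x_j | group1) - mean(x_j | group2)}. Applied to
#' rank-transformed data this is the rank-mean test statistic.
#'
#' @param x numeric matrix (samples x features), already transformed.
#' @param labels logical vector, TRUE for group1.
#' @return numeric vector of per-feature statistics.
#' @export
meandiffStat <- function(x, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    .stopInvalid("both groups must be non-empty")
  colMeans(x[labels, , drop = FALSE]) - colMeans(x[!labels, , drop = FALSE])
}

# All permutations of 1..n as an n! x n matrix (exhaustive nulls for
# continuous label vectors; n is capped upstream).
.allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Build the permutation null distribution of a two-group statistic
#'
#' Each row of the returned matrix is the per-feature statistic under
#' one permuted labeling. Exhaustive mode enumerates every distinct
#' assignment of group sizes (n1, n2) exactly once — \code{choose(n, n1)}
#' assignments, the observed labeling among them; random mode draws
#' uniform label shuffles seeded by \code{seed}.
#'
#' @param x transformed matrix (samples x features).
#' @param labels logical group labels (TRUE = group1).
#' @param nPermutations number of random permutations (ignored in
#'   exhaustive mode).
#' @param seed integer seed for random mode.
#' @param exhaustive enumerate all distinct assignments.
#' @param cap maximum number of assignments allowed in exhaustive mode.
#' @return list with \code{stats} (B x features matrix) and
#'   \code{exhaustive} (logical).
#' @export
permutationNull <- function(x, labels, nPermutations = 1000, seed = NULL,
                            exhaustive = FALSE, cap = 20000) {
  labels <- as.logical(labels)
  n <- length(labels)
  n1 <- sum(labels)
  if (n1 == 0 || n1 == n) .stopInvalid("both groups must be non-empty")
  if (exhaustive) {
    nAssign <- choose(n, n1)
    if (nAssign > cap)
      .stopInvalid(paste0("exhaustive enumeration needs %.0f assignments ",
                          "(cap %d); use random mode"), nAssign, cap)
    cmb <- utils::combn(n, n1)
    G <- matrix(0, ncol(cmb), n)
    G[cbind(rep(seq_len(ncol(cmb)), each = n1), as.vector(cmb))] <- 1
  } else {
    G <- .withSeed(seed, {
      t(replicate(nPermutations, as.numeric(sample(labels))))
    })
  }
  # stat rows for all permutations in one product:
  # mean over group1 - mean over group2 for each labeling row of G
  S <- (G %*% x) / n1 - ((1 - G) %*% x) / (n - n1)
  list(stats = unname(S), exhaustive = exhaustive)
}

#' Permutation p-values from a null-statistic matrix
#'
#' Two-sided p-values compare \code{|s_obs|} with the permuted
#' \code{|s|}; one-sided p-values compare signed values (large positive
#' statistics are extreme). For Monte-Carlo nulls the add-one rule
#' \code{p = (1 + count) / (1 + B)} keeps p strictly positive (required
#' for BH validity); for exhaustive nulls the observed labeling is one
#' of the enumerated rows, so \code{p = count / B}.
#'
#' @param sObs observed per-feature statistics.
#' @param sPerm B x features matrix of permuted statistics.
#' @param twoSided compare absolute values.
#' @param exhaustive sPerm enumerates the full assignment set.
#' @return numeric vector of p-values in (0, 1].
#' @export
permutationPvalues <- function(sObs, sPerm, twoSided = TRUE,
                               exhaustive = FALSE) {
  if (!is.matrix(sPerm) || nrow(sPerm) < 1)
    .stopInvalid("sPerm must be a matrix with at least one row")
  if (twoSided) { sObs <- abs(sObs); sPerm <- abs(sPerm) }
  B <- nrow(sPerm)
  tol <- .statTol * pmax(1, abs(sObs))
  cnt <- colSums(sPerm >= rep(sObs - tol, each = B))
  if (exhaustive) cnt / B else (1 + cnt) / (1 + B)
}

# Smallest achievable p-value per feature given its permutation-null
# support (used by filtered BH to prune the testing family).
.pMinFromNull <- function(sPerm, twoSided = TRUE, exhaustive = FALSE) {
  a <- if (twoSided) abs(sPerm) else sPerm
  B <- nrow(a)
  mx <- apply(a, 2, max)
  tol <- .statTol * pmax(1, mx)
  cnt <- colSums(a >= rep(mx - tol, each = B))
  if (exhaustive) cnt / B else (1 + cnt) / (1 + B)
}

#' Discrete FDR control on the statistic scale
#'
#' For every candidate threshold t (the observed \code{|s|} values), the
#' estimated FDR is
#' \deqn{\widehat{FDR}(t) = \min\!\left(1, \frac{\mathrm{mean}_b\,\#\{j: |s^{perm}_{bj}| \ge t\}}{\max(1, \#\{j: |s^{obs}_j| \ge t\})}\right)}
#' The rejection threshold is the smallest observed \code{|s|} with
#' \eqn{\widehat{FDR} \le \alpha}; all features at or above it are
#' rejected. Feature j's q-value is the smallest \eqn{\widehat{FDR}}
#' over thresholds that would reject it (monotone non-increasing in
#' \code{|s|}). If no threshold qualifies, nothing is rejected.
#'
#' Working on the statistic scale rather than on p-values makes the
#' procedure well-behaved for sparse discrete data, where the p-value
#' support is coarse and p-value-based step-up procedures lose power.
#'
#' @param sObs observed per-feature statistics.
#' @param sPerm B x features matrix of permuted statistics.
#' @param alpha target FDR level.
#' @param twoSided operate on absolute statistics.
#' @return list with \code{rejected} (logical), \code{threshold}
#'   (numeric, NA when nothing qualifies) and \code{qValues}.
#' @export
dsfdrControl <- function(sObs, sPerm, alpha = 0.1, twoSided = TRUE) {
  if (!is.matrix(sPerm) || nrow(sPerm) < 1)
    .stopInvalid("sPerm must be a matrix with at least one row")
  aObs <- if (twoSided) abs(sObs) else sObs
  aPerm <- if (twoSided) abs(sPerm) else sPerm
  B <- nrow(aPerm)
  cands <- sort(unique(aObs))
  tol <- .statTol * pmax(1, cands)
  sortedObs <- sort(aObs)
  R <- length(aObs) - findInterval(cands - tol, sortedObs)
  allPerm <- sort(as.vector(aPerm))
  V <- (length(allPerm) - findInterval(cands - tol, allPerm)) / B
  fdrHat <- pmin(1, V / pmax(1, R))
  qCand <- cummin(fdrHat)        # min over thresholds <= t, ascending t
  idx <- findInterval(aObs + .statTol * pmax(1, aObs), cands)
  qValues <- qCand[pmax(idx, 1)]
  ok <- which(fdrHat <= alpha)
  if (length(ok)) {
    threshold <- cands[min(ok)]
    rejected <- aObs >= threshold - .statTol * max(1, threshold)
  } else {
    threshold <- NA_real_
    rejected <- rep(FALSE, length(aObs))
  }
  list(rejected = rejected, threshold = threshold, qValues = qValues)
}

#' Benjamini-Hochberg step-up control
#'
#' Standard BH: q-values via \code{stats::p.adjust(p, "BH")}; the
#' step-up rejection set is exactly \code{q <= alpha}.
#'
#' @param pValues p-values in (0, 1].
#' @param alpha target FDR level.
#' @return list with \code{rejected} and \code{qValues}.
#' @export
bhControl <- function(pValues, alpha = 0.1) {
  q <- stats::p.adjust(pValues, method = "BH")
  list(rejected = q <= alpha, qValues = q)
}

#' Filtered BH control (minimum-achievable-p family reduction)
#'
#' Features whose smallest achievable p-value (given their discrete
#' permutation-null support) exceeds \code{alpha} can never be rejected
#' and only inflate the multiple-testing burden; they are discarded from
#' the testing family before BH is applied to the remainder. Discarded
#' features get q = 1 and are never rejected. The procedure always
#' rejects at least as many features as plain BH.
#'
#' @param pValues p-values in (0, 1].
#' @param pMinAchievable per-feature smallest attainable p-value.
#' @param alpha target FDR level.
#' @return list with \code{rejected} and \code{qValues}.
#' @export
filteredBhControl <- function(pValues, pMinAchievable, alpha = 0.1) {
  if (length(pValues) != length(pMinAchievable))
    .stopInvalid("pValues and pMinAchievable must have equal length")
  keep <- pMinAchievable <= alpha
  q <- rep(1, length(pValues))
  rejected <- rep(FALSE, length(pValues))
  if (any(keep)) {
    qk <- stats::p.adjust(pValues[keep], method = "BH")
    q[keep] <- qk
    rejected[keep] <- qk <= alpha
  }
  list(rejected = rejected, qValues = q)
}

# shared group-selection logic
.selectGroups <- function(exp, field, group1, group2) {
  md <- sampleData(exp)
  if (!field %in% names(md))
    .stopInvalid("field '%s' not found in sample metadata; available: %s",
                 field, paste(names(md), collapse = ", "))
  if (!is.null(group2) && length(intersect(group1, group2)))
    .stopInvalid("group1 and group2 values overlap: %s",
                 paste(intersect(group1, group2), collapse = ", "))
  vals <- as.character(md[[field]])
  in1 <- vals %in% as.character(group1)
  in2 <- if (is.null(group2)) !in1 & !is.na(vals)
         else vals %in% as.character(group2)
  if (sum(in1) < 2 || sum(in2) < 2)
    .stopInvalid("need at least 2 samples per group (got %d and %d)",
                 sum(in1), sum(in2))
  sel <- which(in1 | in2)
  list(sel = sel, labels = in1[sel])
}

#' Permutation differential-abundance test between two sample groups
#'
#' Selects the samples whose \code{field} value falls in \code{group1}
#' or \code{group2}, applies the per-feature transform (default: ranks,
#' giving the rank-mean test; "binarize" gives the presence/absence
#' test), computes the mean-difference statistic, builds the label-
#' permutation null and controls the FDR with dsFDR (default), BH, or
#' filtered BH.
#'
#' @param exp a FeatureExperiment.
#' @param field sample-metadata column defining the groups.
#' @param group1 values of \code{field} forming group 1.
#' @param group2 values forming group 2; \code{NULL} means all other
#'   samples with a non-missing value.
#' @param transform "rank" (default), "binarize" or "none".
#' @param nPermutations number of random permutations (>= 100).
#' @param alpha target FDR level.
#' @param fdrMethod "dsfdr", "bh" or "filtered_bh".
#' @param seed integer seed; fixed seed + spec gives bit-identical
#'   results.
#' @param twoSided test |statistic| (default) or signed.
#' @param exhaustive enumerate all label assignments instead of
#'   sampling (errors if more than \code{cap} assignments).
#' @param cap exhaustive-enumeration cap.
#' @return a \code{\linkS4class{DiffResult}}.
#' @examples
#' fx <- makeCountExperiment(nPerGroup = c(8, 8), nFeatures = 40,
#'                           nDiff = 5, effectFold = 6, seed = 1)
#' res <- diffAbundance(fx$experiment, "group", "g1", "g2", seed = 1)
#' sum(res@rejected)
#' @export
diffAbundance <- function(exp, field, group1, group2 = NULL,
                          transform = c("rank", "none", "binarize"),
                          nPermutations = 1000, alpha = 0.1,
                          fdrMethod = c("dsfdr", "bh", "filtered_bh"),
                          seed = NULL, twoSided = TRUE,
                          exhaustive = FALSE, cap = 20000) {
  transform <- match.arg(transform)
  fdrMethod <- match.arg(fdrMethod)
  if (nPermutations < 100)
    .stopInvalid("nPermutations must be at least 100")
  grp <- .selectGroups(exp, field, group1, group2)
  x <- .denseData(exp)[grp$sel, , drop = FALSE]
  xt <- perFeatureTransform(x, transform)
  sObs <- meandiffStat(xt, grp$labels)
  null <- permutationNull(xt, grp$labels, nPermutations = nPermutations,
                          seed = seed, exhaustive = exhaustive, cap = cap)
  p <- permutationPvalues(sObs, null$stats, twoSided = twoSided,
                          exhaustive = null$exhaustive)
  ctl <- switch(fdrMethod,
    dsfdr = dsfdrControl(sObs, null$stats, alpha, twoSided = twoSided),
    bh = c(bhControl(p, alpha), threshold = NA_real_),
    filtered_bh = c(filteredBhControl(
      p, .pMinFromNull(null$stats, twoSided, null$exhaustive), alpha),
      threshold = NA_real_))
  spec <- list(test = "diffAbundance", field = field,
               group1 = as.character(group1),
               group2 = if (is.null(group2)) NULL else as.character(group2),
               transform = transform, statistic = "meandiff",
               nPermutations = nPermutations, alpha = alpha,
               fdrMethod = fdrMethod, seed = seed, twoSided = twoSided,
               exhaustive = exhaustive)
  methods::new("DiffResult",
    featureIds = featureIds(exp),
    statObs = unname(sObs),
    pValues = unname(p),
    qValues = unname(ctl$qValues),
    rejected = unname(ctl$rejected),
    direction = unname(ifelse(sObs > 0, "group1", "group2")),
    threshold = if (is.na(ctl$threshold)) NA_real_ else ctl$threshold,
    spec = spec)
}

#' Permutation correlation test against a continuous metadata field
#'
#' Per-feature Spearman (default) or Pearson correlation between
#' abundance and a numeric sample-metadata field; the null is built by
#' permuting the field vector. Samples with a missing field value are
#' dropped with a warning. Zero-variance features get statistic 0 and
#' p = 1. With \code{presence = TRUE} features are binarized first, so
#' the test correlates the field with feature presence rather than
#' abundance.
#'
#' @inheritParams diffAbundance
#' @param method "spearman" or "pearson".
#' @param presence correlate with presence/absence instead of abundance.
#' @return a \code{\linkS4class{DiffResult}}; \code{direction} is
#'   "pos"/"neg" (sign of the observed correlation).
#' @export
correlationTest <- function(exp, field, method = c("spearman", "pearson"),
                            nPermutations = 1000, alpha = 0.1,
                            fdrMethod = c("dsfdr", "bh", "filtered_bh"),
                            seed = NULL, twoSided = TRUE,
                            exhaustive = FALSE, cap = 20000,
                            presence = FALSE) {
  method <- match.arg(method)
  fdrMethod <- match.arg(fdrMethod)
  md <- sampleData(exp)
  if (!field %in% names(md))
    .stopInvalid("field '%s' not found in sample metadata; available: %s",
                 field, paste(names(md), collapse = ", "))
  f <- md[[field]]
  if (!is.numeric(f))
    .stopInvalid("field '%s' is not numeric", field)
  ok <- !is.na(f)
  if (sum(ok) < 3)
    .stopInvalid("need at least 3 samples with non-missing '%s'", field)
  if (!all(ok))
    warning(sprintf("dropping %d sample(s) with missing '%s'", sum(!ok), field))
  x <- .denseData(exp)[ok, , drop = FALSE]
  f <- f[ok]
  if (presence) x <- (x > 0) * 1
  if (method == "spearman") {
    x <- apply(x, 2, rank)
    f <- rank(f)
  }
  n <- length(f)
  corStat <- function(fv) {
    s <- suppressWarnings(stats::cor(x, fv))
    s[is.na(s)] <- 0
    as.vector(s)
  }
  sObs <- corStat(f)
  if (exhaustive) {
    if (factorial(n) > cap)
      .stopInvalid(paste0("exhaustive enumeration needs %.0f permutations ",
                          "(cap %d); use random mode"), factorial(n), cap)
    P <- t(matrix(f[t(.allPermutations(n))], ncol = n, byrow = TRUE))
  } else {
    P <- .withSeed(seed, replicate(nPermutations, sample(f)))
  }
  S <- suppressWarnings(stats::cor(x, P))   # features x B
  S[is.na(S)] <- 0
  sPerm <- t(S)
  p <- permutationPvalues(sObs, sPerm, twoSided = twoSided,
                          exhaustive = exhaustive)
  ctl <- switch(fdrMethod,
    dsfdr = dsfdrControl(sObs, sPerm, alpha, twoSided = twoSided),
    bh = c(bhControl(p, alpha), threshold = NA_real_),
    filtered_bh = c(filteredBhControl(
      p, .pMinFromNull(sPerm, twoSided, exhaustive), alpha),
      threshold = NA_real_))
  spec <- list(test = "correlationTest", field = field, method = method,
               presence = presence, nPermutations = nPermutations,
               alpha = alpha, fdrMethod = fdrMethod, seed = seed,
               twoSided = twoSided, exhaustive = exhaustive)
  methods::new("DiffResult",
    featureIds = featureIds(exp),
    statObs = unname(sObs),
    pValues = unname(p),
    qValues = unname(ctl$qValues),
    rejected = unname(ctl$rejected),
    direction = unname(ifelse(sObs >= 0, "pos", "neg")),
    threshold = if (is.na(ctl$threshold)) NA_real_ else ctl$threshold,
    spec = spec)
}

#' Tabulate a DiffResult
#'
#' @param x a DiffResult.
#' @param row.names,optional,... passed on for S3 compatibility; unused.
#' @return data.frame with columns feature, stat, p, q, rejected,
#'   direction, in the experiment's feature order.
#' @export
as.data.frame.DiffResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(feature = x@featureIds, stat = x@statObs, p = x@pValues,
             q = x@qValues, rejected = x@rejected, direction = x@direction,
             stringsAsFactors = FALSE)
}
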