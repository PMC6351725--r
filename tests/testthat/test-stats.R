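# Independent oracles used below: a brute-force threshold scan for the
# discrete FDR procedure, a quadratic step-up implementation of BH, and
# exhaustive label enumeration for p-values.

naiveBH <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i * alpha / m) k <- i
  rejected <- rep(FALSE, m)
  if (k > 0) rejected[ord[seq_len(k)]] <- TRUE
  q <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    r <- sum(p <= p[j])
    q[j] <- min(1, min(vapply(seq(r, m), function(i)
      sort(p)[i] * m / i, 0)))
  }
  list(rejected = rejected, q = q)
}

naiveDsfdr <- function(sObs, sPerm, alpha) {
  a <- abs(sObs); ap <- abs(sPerm)
  cands <- sort(unique(a))
  fdr <- vapply(cands, function(t) {
    V <- mean(apply(ap, 1, function(row) sum(row >= t - 1e-9)))
    R <- sum(a >= t - 1e-9)
    min(1, V / max(1, R))
  }, 0)
  ok <- which(fdr <= alpha)
  if (!length(ok)) return(rep(FALSE, length(a)))
  a >= cands[min(ok)] - 1e-9
}

test_that("per-feature transforms follow the mid-rank and presence rules", {
  x <- matrix(c(5, 5, 1), 3, 1)
  expect_equal(perFeatureTransform(x, "rank")[, 1], c(2.5, 2.5, 1))
  expect_equal(perFeatureTransform(matrix(7, 4, 1), "rank")[, 1],
               rep(2.5, 4))
  expect_equal(perFeatureTransform(matrix(1:5, 5, 1), "rank")[, 1], 1:5)
  expect_equal(perFeatureTransform(matrix(c(0, 2, 0.1), 3, 1), "binarize")[, 1],
               c(0, 1, 1))
  expect_identical(perFeatureTransform(x, "none"), x)
})

test_that("mean-difference statistic is the group-mean contrast and antisymmetric", {
  x <- cbind(c(1, 1, 0, 0), c(2, 2, 2, 2))
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(unname(meandiffStat(x, labels)), c(1, 0))
  expect_equal(meandiffStat(x, labels), -meandiffStat(x, !labels))
  expect_error(meandiffStat(x, rep(TRUE, 4)), "non-empty")
})

test_that("exhaustive null enumerates every distinct assignment exactly once", {
  x <- matrix(rnorm(8 * 3), 8, 3)
  labels <- rep(c(TRUE, FALSE), each = 4)
  nl <- permutationNull(x, labels, exhaustive = TRUE)
  expect_equal(nrow(nl$stats), choose(8, 4))   # 70
  # the observed labeling is one of the enumerated rows
  sObs <- meandiffStat(x, labels)
  expect_true(any(apply(nl$stats, 1, function(r)
    max(abs(r - sObs)) < 1e-12)))
  # constant feature gives an identically-zero null column
  xc <- cbind(x, 5)
  nlc <- permutationNull(xc, labels, exhaustive = TRUE)
  expect_true(all(nlc$stats[, 4] == 0))
  # cap exceeded suggests random mode
  big <- matrix(0, 20, 1)
  expect_error(permutationNull(big, rep(c(TRUE, FALSE), each = 10),
                               exhaustive = TRUE),
               "random mode")
})

test_that("p-values follow the add-one rule (random) and count/B (exhaustive)", {
  # observed larger than every permuted value, B = 999
  sPerm <- matrix(rnorm(999) * 0.01, 999, 1)
  expect_equal(permutationPvalues(10, sPerm), 1 / 1000)
  # zero observed statistic under a symmetric null -> p = 1
  expect_equal(permutationPvalues(0, sPerm), 1)
  # perfect separation, exhaustive 70-assignment null, rank transform
  x <- matrix(c(10, 11, 12, 13, 1, 2, 3, 4), ncol = 1)
  labels <- rep(c(TRUE, FALSE), each = 4)
  xt <- perFeatureTransform(x, "rank")
  s <- meandiffStat(xt, labels)
  nl <- permutationNull(xt, labels, exhaustive = TRUE)
  p <- permutationPvalues(s, nl$stats, exhaustive = TRUE)
  expect_equal(p, 2 / 70)               # only the true split and its mirror
})

test_that("Monte-Carlo p-values sit in the binomial 99% CI of exhaustive ones", {
  fx <- makeCountExperiment(nPerGroup = c(4, 4), nFeatures = 20,
                            nDiff = 3, effectFold = 8, seed = 42)
  x <- abundance(fx$experiment)
  labels <- sampleData(fx$experiment)$group == "g1"
  xt <- perFeatureTransform(x, "rank")
  s <- meandiffStat(xt, labels)
  ex <- permutationNull(xt, labels, exhaustive = TRUE)
  pEx <- permutationPvalues(s, ex$stats, exhaustive = TRUE)
  mc <- permutationNull(xt, labels, nPermutations = 999, seed = 5)
  pMc <- permutationPvalues(s, mc$stats)
  cnt <- pMc * 1000 - 1                 # invert the add-one rule
  # joint check over 20 features: per-feature level chosen so the
  # familywise pass rate stays near 1
  lo <- qbinom(0.0005, 999, pEx)
  hi <- qbinom(0.9995, 999, pEx)
  expect_true(all(cnt >= lo & cnt <= hi))
})

test_that("dsFDR handles the degenerate and capped cases as specified", {
  sObs <- c(3, 1, 0.5, 2)
  # permutation rows identical to the observed vector: FDRhat = 1, no rejections
  sPerm <- matrix(rep(sObs, each = 50), 50, 4)
  ctl <- dsfdrControl(sObs, sPerm, alpha = 0.1)
  expect_false(any(ctl$rejected))
  expect_true(all(ctl$qValues >= 1 - 1e-12))
  # alpha = 1 with the min(1, .) cap rejects everything at/above min |s|
  ctl2 <- dsfdrControl(sObs, sPerm, alpha = 1)
  expect_true(all(ctl2$rejected))
  # rejected features always satisfy q <= alpha
  set.seed(2)
  sp <- matrix(rnorm(200 * 30), 200, 30)
  so <- c(rnorm(25), 5, 6, 7, 8, 9)
  ctl3 <- dsfdrControl(so, sp, alpha = 0.1)
  expect_true(all(ctl3$qValues[ctl3$rejected] <= 0.1 + 1e-12))
  # q is monotone non-increasing in |s|
  ordQ <- ctl3$qValues[order(abs(so))]
  expect_true(all(diff(ordQ) <= 1e-12))
})

test_that("dsFDR rejection set equals the brute-force threshold scan", {
  for (seed in 1:5) {
    fx <- makeCountExperiment(nPerGroup = c(4, 4), nFeatures = 30,
                              nDiff = 5, effectFold = 6, seed = seed)
    x <- abundance(fx$experiment)
    labels <- sampleData(fx$experiment)$group == "g1"
    xt <- perFeatureTransform(x, "rank")
    s <- meandiffStat(xt, labels)
    nl <- permutationNull(xt, labels, exhaustive = TRUE)
    ctl <- dsfdrControl(s, nl$stats, alpha = 0.1)
    expect_identical(unname(ctl$rejected), naiveDsfdr(s, nl$stats, 0.1))
  }
})

test_that("dsFDR rejections grow with alpha", {
  fx <- makeCountExperiment(nPerGroup = c(6, 6), nFeatures = 50,
                            nDiff = 8, effectFold = 4, seed = 17)
  x <- abundance(fx$experiment)
  labels <- sampleData(fx$experiment)$group == "g1"
  xt <- perFeatureTransform(x, "rank")
  s <- meandiffStat(xt, labels)
  nl <- permutationNull(xt, labels, nPermutations = 500, seed = 1)
  prev <- rep(FALSE, 50)
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    cur <- dsfdrControl(s, nl$stats, alpha)$rejected
    expect_true(all(prev <= cur))       # superset of smaller alpha
    prev <- cur
  }
})

test_that("BH control matches a quadratic reference implementation", {
  expect_true(bhControl(0.04, alpha = 0.05)$rejected)
  allOne <- bhControl(rep(1, 10), alpha = 0.1)
  expect_false(any(allOne$rejected))
  expect_true(all(allOne$qValues == 1))
  set.seed(13)
  for (r in 1:5) {
    p <- c(runif(30)^2, runif(10))
    got <- bhControl(p, alpha = 0.1)
    ref <- naiveBH(p, 0.1)
    expect_identical(unname(got$rejected), ref$rejected)
    expect_equal(unname(got$qValues), ref$q)
  }
})

test_that("filtered BH prunes untestable features and never trails BH", {
  # all features attain p_min <= alpha -> identical to BH
  set.seed(19)
  p <- runif(40)^1.5
  pmin <- rep(0.001, 40)
  a <- filteredBhControl(p, pmin, alpha = 0.1)
  b <- bhControl(p, alpha = 0.1)
  expect_identical(a$rejected, unname(b$rejected))
  # a feature present in one sample has p_min = 1 under the binarized
  # exhaustive null (every assignment gives the same |statistic|)
  x <- matrix(0, 8, 1); x[1, 1] <- 7
  labels <- rep(c(TRUE, FALSE), each = 4)
  xb <- perFeatureTransform(x, "binarize")
  nl <- permutationNull(xb, labels, exhaustive = TRUE)
  pmin1 <- microexplore:::.pMinFromNull(nl$stats, exhaustive = TRUE)
  expect_equal(pmin1, 1)
  out <- filteredBhControl(0.4, pmin1, alpha = 0.1)
  expect_false(out$rejected)
  expect_equal(out$qValues, 1)
  # on random mixtures, filtering rejects at least as much as BH
  for (r in 1:5) {
    p <- c(runif(20)^3, runif(20))
    pmin <- sample(c(0.001, 0.5), 40, replace = TRUE)
    pmin <- pmin(pmin, p)               # achievable minimum never exceeds p
    fb <- filteredBhControl(p, pmin, 0.1)
    bh <- bhControl(p, 0.1)
    expect_gte(sum(fb$rejected), sum(bh$rejected))
  }
  expect_error(filteredBhControl(runif(3), runif(2), 0.1), "equal length")
})

test_that("diffAbundance handles constant data and presence/absence direction", {
  m <- matrix(5, 8, 3, dimnames = list(paste0("s", 1:8), paste0("f", 1:3)))
  smd <- data.frame(group = rep(c("a", "b"), each = 4),
                    row.names = paste0("s", 1:8))
  fe <- featureExperiment(m, smd)
  res <- diffAbundance(fe, "group", "a", "b", transform = "none",
                       nPermutations = 200, seed = 1)
  expect_true(all(res@statObs == 0))
  expect_false(any(res@rejected))
  # feature present only in group1 points at group1 under binarize
  m2 <- m; m2[1:4, 1] <- 9; m2[5:8, 1] <- 0; m2[, 2] <- rpois(8, 4) + 1
  fe2 <- featureExperiment(m2, smd)
  res2 <- diffAbundance(fe2, "group", "a", "b", transform = "binarize",
                        nPermutations = 200, seed = 1)
  expect_identical(res2@direction[1], "group1")
  # invalid group specs
  expect_error(diffAbundance(fe, "group", "a", "a"), "overlap")
  expect_error(diffAbundance(fe, "group", "zz", "b"), "at least 2")
  expect_error(diffAbundance(fe, "nope", "a", "b"), "available")
})

test_that("diffAbundance recovers a planted signal and is seed-deterministic", {
  fx <- makeCountExperiment(nPerGroup = c(10, 10), nFeatures = 60,
                            nDiff = 6, effectFold = 5, seed = 99)
  r1 <- diffAbundance(fx$experiment, "group", "g1", "g2",
                      nPermutations = 500, seed = 7)
  r2 <- diffAbundance(fx$experiment, "group", "g1", "g2",
                      nPermutations = 500, seed = 7)
  expect_identical(r1@pValues, r2@pValues)
  expect_identical(r1@qValues, r2@qValues)
  expect_identical(r1@rejected, r2@rejected)
  expect_true(all(which(fx$truth) %in% which(r1@rejected)))
  expect_identical(r1@direction[fx$truth], rep("group1", 6))
  # group2 = NULL takes the complement
  rc <- diffAbundance(fx$experiment, "group", "g1", NULL,
                      nPermutations = 500, seed = 7)
  expect_identical(rc@rejected, r1@rejected)
})

test_that("correlation test: exact exhaustive p, antisymmetry, degenerate features", {
  m <- cbind(f1 = 1:6, f2 = rep(3, 6))    # monotone and constant features
  rownames(m) <- paste0("s", 1:6)
  fe <- featureExperiment(m, data.frame(fld = c(2, 4, 6, 8, 10, 12),
                                        row.names = rownames(m)))
  res <- correlationTest(fe, "fld", method = "spearman", exhaustive = TRUE)
  expect_equal(res@pValues[1], 2 / 720)   # identity and reversal only
  expect_equal(res@statObs[2], 0)         # zero-variance feature
  expect_equal(res@pValues[2], 1)
  expect_identical(res@direction[1], "pos")
  # negating the field negates Pearson statistics
  fe2 <- featureExperiment(m, data.frame(fld = -c(2, 4, 6, 8, 10, 12),
                                         row.names = rownames(m)))
  rp <- correlationTest(fe, "fld", method = "pearson",
                        nPermutations = 200, seed = 3)
  rn <- correlationTest(fe2, "fld", method = "pearson",
                        nPermutations = 200, seed = 3)
  expect_equal(rp@statObs, -rn@statObs)
  # non-numeric and missing-value handling
  feBad <- featureExperiment(m, data.frame(fld = letters[1:6],
                                           row.names = rownames(m)))
  expect_error(correlationTest(feBad, "fld"), "not numeric")
  feNA <- featureExperiment(m, data.frame(fld = c(1, 2, 3, 4, NA, 6),
                                          row.names = rownames(m)))
  expect_warning(correlationTest(feNA, "fld", nPermutations = 200, seed = 1),
                 "missing")
})

test_that("type-I error stays near alpha on null fixtures for all corrections", {
  nFix <- 30
  fdp <- matrix(0, nFix, 3, dimnames = list(NULL, c("dsfdr", "bh", "filtered_bh")))
  for (s in seq_len(nFix)) {
    fx <- makeCountExperiment(nPerGroup = c(10, 10), nFeatures = 50,
                              nDiff = 0, effectFold = 1, seed = 2000 + s)
    for (mth in colnames(fdp)) {
      r <- diffAbundance(fx$experiment, "group", "g1", "g2",
                         nPermutations = 300, fdrMethod = mth, seed = s)
      fdp[s, mth] <- mean(r@rejected)   # every rejection is false
    }
  }
  mcse <- sqrt(0.1 * 0.9 / nFix)
  for (mth in colnames(fdp))
    expect_lte(mean(fdp[, mth] > 0), 0.1 + 3 * mcse)
})
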