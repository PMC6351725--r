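test_that("TSS scales every sample to the requested total and preserves ratios", {
  fe <- randomExperiment(nS = 50, nF = 100, seed = 3)
  out <- normalizeTSS(fe, 10000)
  expect_lt(max(abs(rowSums(abundance(out)) - 10000)), 1e-6)
  expect_equal(normalizedTotal(out), 10000)
  # within-sample ratios conserved
  m0 <- abundance(fe); m1 <- abundance(out)
  i <- which(m0[1, ] > 0)[1:2]
  expect_equal(m1[1, i[1]] / m1[1, i[2]], m0[1, i[1]] / m0[1, i[2]])
  # idempotence within tolerance
  out2 <- normalizeTSS(out, 10000)
  expect_lt(max(abs(abundance(out2) - abundance(out))), 1e-9)
  # forced tiny example
  one <- featureExperiment(matrix(c(1, 3), 1, 2))
  expect_equal(unname(abundance(normalizeTSS(one, 10000))[1, ]), c(2500, 7500))
  # all-zero sample errors unless dropped
  z <- featureExperiment(matrix(c(0, 0, 1, 2), 2, 2, byrow = TRUE))
  expect_error(normalizeTSS(z, 100), "all-zero")
  expect_warning(zd <- normalizeTSS(z, 100, dropZero = TRUE), "dropping")
  expect_equal(nSamples(zd), 1)
})

test_that("outlier-excluding TSS follows the iterative exclusion rule", {
  fe <- featureExperiment(matrix(c(90, 5, 5), 1, 3))
  out <- suppressMessages(normalizeTSSOutliers(fe, total = 100,
                                               outlierFraction = 0.5))
  expect_equal(unname(abundance(out)[1, ]), c(900, 50, 50))
  # no feature above the fraction -> identical to plain TSS
  flat <- randomExperiment(nS = 5, nF = 50, seed = 2)
  a <- suppressMessages(normalizeTSSOutliers(flat, 10000, 0.5))
  b <- normalizeTSS(flat, 10000)
  expect_lt(max(abs(abundance(a) - abundance(b))), 1e-9)
  # outlierFraction = 1 is vacuous
  c1 <- suppressMessages(normalizeTSSOutliers(flat, 10000, 1))
  expect_lt(max(abs(abundance(c1) - abundance(b))), 1e-9)
  # a sample where everything is excluded errors with the sample name
  lone <- featureExperiment(matrix(c(100, 1), 1, 2,
                                   dimnames = list("sampleZ", c("a", "b"))))
  expect_error(suppressMessages(normalizeTSSOutliers(lone, 100, 0.0001)),
               "sampleZ")
})

test_that("CLR centers every sample at zero and flags non-count output", {
  flat <- featureExperiment(matrix(4, 2, 3))
  expect_equal(unname(abundance(transformCLR(flat))), matrix(0, 2, 3))
  fe <- randomExperiment(nS = 100, nF = 200, seed = 5, sparsity = 0.5)
  out <- transformCLR(fe)
  expect_lt(max(abs(rowSums(abundance(out)))), 1e-9)
  expect_true(out@nonCount)
  expect_error(transformCLR(fe, pseudocount = 0), "positive")
  # scale invariance of the shifted data: clr(k * (x + c) - c + ...) --
  # multiplying (x + c) by k shifts every log by log(k), removed by centering
  m <- abundance(fe)
  shifted <- log(m + 1) + log(7)       # as if (x+1) scaled by 7
  manual <- shifted - rowMeans(shifted)
  expect_lt(max(abs(manual - abundance(out))), 1e-9)
})

test_that("log transform floors at the cutoff and preserves ordering", {
  fe <- featureExperiment(matrix(c(0, 1024, 3, 1), 2, 2))
  out <- abundance(transformLog(fe, base = 2, minCutoff = 1))
  expect_equal(out[1, 1], 0)            # x = 0 -> log2(1) = 0
  expect_equal(out[2, 1], 10)           # log2(1024)
  expect_error(transformLog(fe, minCutoff = 0), "positive")
  # order preservation on random matrices
  fe2 <- randomExperiment(nS = 100, nF = 200, seed = 11, sparsity = 0.3)
  m <- abundance(fe2); lm <- abundance(transformLog(fe2))
  pairs <- cbind(sample(length(m), 500), sample(length(m), 500))
  expect_true(all(sign(lm[pairs[, 1]] - lm[pairs[, 2]]) ==
                  sign(m[pairs[, 1]] - m[pairs[, 2]]) |
                  lm[pairs[, 1]] == lm[pairs[, 2]]))
})

test_that("binarize uses strict inequality and is idempotent", {
  fe <- featureExperiment(matrix(c(0, 0.5, 3), 1, 3))
  expect_equal(unname(abundance(binarize(fe))[1, ]), c(0, 1, 1))
  b1 <- binarize(fe); b2 <- binarize(b1)
  expect_identical(abundance(b1), abundance(b2))
  high <- binarize(fe, cutoff = 10)
  expect_true(all(abundance(high) == 0))
})

test_that("unit scaling gives population mean-0 sd-1 features, zeros for constants", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 3, 2)
  fe <- featureExperiment(m)
  s <- scaleFeaturesUnit(fe)
  expect_lt(abs(mean(s[, 1])), 1e-12)
  expect_equal(mean(s[, 1]^2), 1)       # population variance
  expect_true(all(s[, 2] == 0))         # constant column
  fe2 <- randomExperiment(nS = 40, nF = 30, seed = 9)
  s2 <- scaleFeaturesUnit(fe2)
  expect_lt(max(abs(colMeans(s2))), 1e-9)
  expect_lt(max(abs(colMeans(s2^2) - 1)), 1e-9)
})

test_that("every transform appends exactly one history record with its parameters", {
  fe <- tinyExperiment()
  checks <- list(
    list(f = function(e) normalizeTSS(e, 500), op = "normalizeTSS",
         key = "total", val = 500),
    list(f = function(e) transformCLR(e, 2), op = "transformCLR",
         key = "pseudocount", val = 2),
    list(f = function(e) transformLog(e, 10, 1), op = "transformLog",
         key = "base", val = 10),
    list(f = function(e) binarize(e, 1), op = "binarize",
         key = "cutoff", val = 1))
  for (ck in checks) {
    out <- ck$f(fe)
    expect_length(opHistory(out), 1)
    rec <- opHistory(out)[[1]]
    expect_identical(rec$op_name, ck$op)
    expect_equal(rec$params[[ck$key]], ck$val)
  }
})
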