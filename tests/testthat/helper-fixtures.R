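# Small in-code fixtures shared across test files.

# tiny deterministic experiment: 6 samples x 4 features with metadata
tinyExperiment <- function(sparse = FALSE) {
  m <- matrix(c(
    5, 0, 2, 1,
    0, 3, 0, 4,
    1, 1, 1, 1,
    8, 0, 0, 2,
    0, 6, 3, 0,
    2, 2, 2, 2), nrow = 6, byrow = TRUE,
    dimnames = list(paste0("s", 1:6), paste0("f", 1:4)))
  smd <- data.frame(origin = c("Pond", "Stream", "Pond", "Pond",
                               "Stream", "Stream"),
                    plate = c("pa", "pa", "pb", "pb", "pa", "pb"),
                    depth = c(8, 7, 4, 10, 9, 8),
                    row.names = rownames(m), stringsAsFactors = FALSE)
  fmd <- data.frame(taxon = c("A", "B", NA, "D"),
                    row.names = colnames(m), stringsAsFactors = FALSE)
  featureExperiment(m, smd, fmd, sparse = sparse)
}

# random count experiment without planted structure
randomExperiment <- function(nS = 20, nF = 30, seed = 1, sparsity = 0) {
  set.seed(seed)
  m <- matrix(rpois(nS * nF, 40), nS, nF)
  if (sparsity > 0) m[runif(length(m)) < sparsity] <- 0
  dimnames(m) <- list(sprintf("s%02d", seq_len(nS)),
                      sprintf("f%02d", seq_len(nF)))
  featureExperiment(m)
}

# small annotation store built by hand
handStore <- function() {
  tf <- tempfile(fileext = ".jsonl")
  recs <- c(
    '{"annotation_id":"a1","type":"higher_in","terms":["skin"],"experiment":"e1","features":["f1","f2"]}',
    '{"annotation_id":"a2","type":"lower_in","terms":["feces"],"experiment":"e1","features":["f2"]}',
    '{"annotation_id":"a3","type":"common","terms":["skin","saliva"],"experiment":"e2","features":["f1","f3"]}',
    '{"annotation_id":"a4","type":"contamination","terms":[],"experiment":"e3","features":["f4"]}')
  writeLines(recs, tf)
  loadStore(tf)
}

expect_synced <- function(exp) {
  expect_true(methods::validObject(exp))
  expect_identical(rownames(abundance(exp)), sampleIds(exp))
  expect_identical(colnames(abundance(exp)), featureIds(exp))
}
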