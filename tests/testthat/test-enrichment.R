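test_that("annotation stores load, validate and round-trip", {
  store <- handStore()
  expect_length(store@annotations, 4)
  # empty file -> empty store
  tf <- tempfile(); writeLines(character(0), tf)
  expect_length(loadStore(tf)@annotations, 0)
  # duplicate annotation ids rejected
  writeLines(rep('{"annotation_id":"a1","type":"common","terms":["t"],"features":["f1"]}', 2), tf)
  expect_error(loadStore(tf), "duplicated annotation")
  # unknown type rejected
  writeLines('{"annotation_id":"a9","type":"sideways","terms":["t"],"features":["f1"]}', tf)
  expect_error(loadStore(tf), "unknown annotation type")
  # malformed JSON names the record
  writeLines(c('{"annotation_id":"ok","type":"common","terms":["t"],"features":["f1"]}',
               "{broken"), tf)
  expect_error(loadStore(tf), "record 2")
  # save/load identity
  out <- tempfile(fileext = ".jsonl")
  saveStore(store, out)
  again <- loadStore(out)
  expect_identical(again@annotations, store@annotations)
  expect_identical(again@index, store@index)
  # tsv dialect parses the same records
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("annotation_id\ttype\tterms\texperiment\tfeatures",
               "a1\thigher_in\tskin\te1\tf1;f2",
               "a3\tcommon\tskin;saliva\te2\tf1;f3"), tsv)
  st <- loadStore(tsv)
  expect_identical(st@annotations$a3$terms, c("skin", "saliva"))
})

test_that("feature lookup equals a linear scan over annotations", {
  store <- handStore()
  expect_length(featureAnnotations(store, "not-there"), 0)
  expect_length(featureAnnotations(store, "f1"), 2)
  # oracle: scan every annotation for membership, on a random store
  ids <- sprintf("g%02d", 1:30)
  rnd <- makeAnnotationStore(ids, nTerms = 20, nDecoyAnnotations = 50, seed = 4)
  for (f in sample(ids, 10)) {
    viaIndex <- vapply(featureAnnotations(rnd, f), `[[`, "", "annotation_id")
    viaScan <- names(Filter(function(a) f %in% a$features, rnd@annotations))
    expect_setequal(viaIndex, viaScan)
  }
})

test_that("term scores apply the +2/+1/-2 weights additively", {
  store <- handStore()
  sc <- termScoreMatrix(store, c("f1", "f2", "f3", "f4", "f9"))
  expect_equal(sc["skin", "f1"], 2 + 1)   # higher_in (+2) and common (+1)
  expect_equal(sc["skin", "f2"], 2)
  expect_equal(sc["feces", "f2"], -2)     # lower_in
  expect_equal(sc["saliva", "f3"], 1)
  expect_true(all(sc[, "f4"] == 0))       # contamination contributes 0
  expect_true(all(sc[, "f9"] == 0))       # unannotated feature: zero column
  # additivity of two common annotations sharing a term
  tf <- tempfile()
  writeLines(c('{"annotation_id":"c1","type":"common","terms":["gut"],"features":["fx"]}',
               '{"annotation_id":"c2","type":"common","terms":["gut"],"features":["fx"]}'), tf)
  expect_equal(termScoreMatrix(loadStore(tf), "fx")["gut", "fx"], 2)
})

test_that("term enrichment finds a planted term and respects symmetry", {
  ids <- sprintf("f%02d", 1:40)
  store <- makeAnnotationStore(ids, nTerms = 50,
    planted = list(term = "planted", features = ids[1:20], type = "higher_in"),
    nDecoyAnnotations = 60, seed = 11)
  res <- enrichTerms(store, ids[1:20], ids[21:40], nPermutations = 500,
                     seed = 11)
  pl <- res[res$term == "planted", ]
  expect_true(pl$rejected)
  expect_lte(pl$q, 0.1)
  expect_identical(pl$enrichedGroup, "group1")
  expect_equal(pl$meanScore1, 2); expect_equal(pl$meanScore2, 0)
  # swapping the groups negates statistics, keeps the significant set
  swp <- enrichTerms(store, ids[21:40], ids[1:20], nPermutations = 500,
                     seed = 11)
  expect_equal(swp$stat[match(res$term, swp$term)], -res$stat)
  # empty store -> empty result
  tf <- tempfile(); writeLines(character(0), tf)
  expect_equal(nrow(enrichTerms(loadStore(tf), "a", "b")), 0)
  expect_error(enrichTerms(store, ids[1:5], ids[3:8]), "overlap")
})

test_that("a group-symmetric store yields no significant terms", {
  # identical score patterns in both groups: exchangeable by construction
  tf <- tempfile()
  recs <- vapply(1:10, function(i) sprintf(
    '{"annotation_id":"s%d","type":"common","terms":["t%d"],"features":["f%02d","f%02d"]}',
    i, i, i, i + 10), "")
  writeLines(recs, tf)
  store <- loadStore(tf)
  res <- enrichTerms(store, sprintf("f%02d", 1:10), sprintf("f%02d", 11:20),
                     nPermutations = 500, seed = 2)
  expect_true(all(res$stat == 0))
  expect_false(any(res$rejected))
})

test_that("contaminant flagging writes the three-way status column", {
  store <- handStore()
  m <- matrix(1, 2, 5, dimnames = list(c("s1", "s2"),
                                       c("f1", "f2", "f4", "f9", "f3")))
  fe <- flagContaminants(store, featureExperiment(m))
  status <- featureData(fe)$annotationStatus
  names(status) <- featureIds(fe)
  expect_identical(unname(status[c("f1", "f4", "f9")]),
                   c("annotated", "contaminant", "none"))
  # usable downstream as a metadata filter
  clean <- filterByMetadata(fe, "features", "annotationStatus",
                            "contaminant", negate = TRUE)
  expect_false("f4" %in% featureIds(clean))
})

test_that("most common term picks the top-scoring candidate with stable ties", {
  tf <- tempfile()
  writeLines(c(
    '{"annotation_id":"k1","type":"higher_in","terms":["skin"],"features":["fA"]}',
    '{"annotation_id":"k2","type":"higher_in","terms":["skin"],"features":["fA"]}',
    '{"annotation_id":"k3","type":"common","terms":["saliva"],"features":["fA"]}',
    '{"annotation_id":"k4","type":"higher_in","terms":["feces"],"features":["fB"]}',
    '{"annotation_id":"k5","type":"higher_in","terms":["saliva"],"features":["fB"]}',
    '{"annotation_id":"k6","type":"lower_in","terms":["skin"],"features":["fC"]}'), tf)
  store <- loadStore(tf)
  cands <- c("skin", "saliva", "feces")
  expect_identical(mostCommonTerm(store, "fA", cands), "skin")   # 4 vs 1
  expect_identical(mostCommonTerm(store, "fB", cands), "saliva") # tie -> earlier
  expect_identical(mostCommonTerm(store, "fC", cands), "other")  # only negative
  expect_identical(mostCommonTerm(store, "unknown", cands), "other")
  expect_error(mostCommonTerm(store, "fA", character(0)), "non-empty")
})
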