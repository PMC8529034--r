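test_that("candidate accuracy is the answered-set membership fraction", {
  ranked <- list(i1 = c("puni", "buni"),
                 i2 = c("gowa-gowa", "puni"),
                 i3 = c("sara-sara", "puni"),
                 i4 = c("fuwa-fuwa", "gowa-gowa"),
                 i5 = c("zara-zara", "boko-boko"))
  answered <- list(i1 = c("puni", "buni"), i2 = "gowa-gowa",
                   i3 = "sara-sara", i4 = "fuwa-fuwa", i5 = "mosa-mosa")
  expect_equal(candidateAccuracy(ranked, answered, rank = 1), 0.8)
  expect_equal(candidateAccuracy(ranked, answered, rank = 2), 0.2)
  # candidates drawn from each image's own answers are always correct
  expect_equal(candidateAccuracy(lapply(answered, `[`, 1), answered), 1.0)
  # membership is canonical: spelling variants still count
  expect_equal(candidateAccuracy(list(i1 = "gowagowa"),
                                 list(i1 = "gowa-gowa")), 1.0)
  expect_error(candidateAccuracy(ranked, answered[1:3]), "no answered")
})

test_that("model evaluation agrees with a brute-force oracle ranking", {
  corpus <- genCorpus(8, seed = 55)
  ann <- corpusAnnotations(corpus)
  lex <- buildLexicon(ann)
  ts <- makePairs(corpusImages(corpus), ann)
  fit <- trainModel(ts, smallModelConfig(seed = 55, epochs = 2L))
  res <- evaluateModel(fit, corpusImages(corpus), lex,
                       answered = answeredSets(ann), ranks = 3L)
  expect_setequal(unique(res$image_id), names(corpusImages(corpus)))
  expect_true(all(res$rank %in% 1:3))
  # per image: ascending losses, and the exact brute-force top-3
  outs <- predictPhonemes(fit, corpusImages(corpus))
  for (id in names(corpusImages(corpus))) {
    sub <- res[res$image_id == id, ]
    expect_false(is.unsorted(sub$loss))
    brute <- vapply(lex$ssw, function(w)
      oracleLoss(outs[id, ], phonoBits(encodeSSW(w))), numeric(1))
    ord <- order(brute, -lex$count, lex$ssw)[1:3]
    expect_equal(sub$candidate, lex$ssw[ord])
    expect_equal(sub$loss, unname(brute[ord]), tolerance = 1e-9)
    expect_equal(sub$correct, lex$ssw[ord] %in% answeredSets(ann)[[id]])
  }
  # accuracy from the results table matches candidateAccuracy arithmetic
  for (r in 1:3)
    expect_equal(candidateAccuracy(res, answeredSets(ann), rank = r),
                 mean(res$correct[res$rank == r]))
})

test_that("accuracy is invariant to lexicon order permutations", {
  corpus <- genCorpus(6, seed = 63)
  ann <- corpusAnnotations(corpus)
  lex <- buildLexicon(ann)
  ts <- makePairs(corpusImages(corpus), ann)
  fit <- trainModel(ts, smallModelConfig(seed = 63, epochs = 2L))
  shuffled <- lex[sample(nrow(lex)), ]
  r1 <- evaluateModel(fit, corpusImages(corpus), lex,
                      answered = answeredSets(ann))
  r2 <- evaluateModel(fit, corpusImages(corpus), shuffled,
                      answered = answeredSets(ann))
  expect_equal(r1, r2)
})

test_that("accuracy curves come from tracked training epochs", {
  corpus <- genCorpus(10, seed = 77)
  ann <- corpusAnnotations(corpus)
  ts <- makePairs(corpusImages(corpus), ann)
  ids <- names(corpusImages(corpus))
  track <- list(lexicon = buildLexicon(ann), answered = answeredSets(ann))
  fit <- trainModel(ts, smallModelConfig(seed = 77, epochs = 3L),
                    testImages = ids[1:2], trackAccuracy = track)
  curve <- accuracyCurves(fit)
  expect_equal(nrow(curve), 3L)
  expect_true(all(curve$acc1 >= 0 & curve$acc1 <= 1))
  expect_true(all(curve$acc2 >= 0 & curve$acc2 <= 1))
  plain <- trainModel(ts, smallModelConfig(seed = 77, epochs = 2L))
  expect_error(accuracyCurves(plain), "tracking")
})
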