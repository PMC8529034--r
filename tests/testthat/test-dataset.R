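flatImage <- function(h, w) array(0.5, c(h, w, 3))

test_that("mark clustering yields one clamped crop per agreeing cluster", {
  img <- flatImage(384, 512)
  # three participants on one spot -> exactly one 150x150 crop
  marks <- data.frame(participant_id = c("a", "b", "c"),
                      x = c(250, 255, 252), y = c(190, 188, 195))
  crops <- cropMarkedRegions(img, marks)
  expect_length(crops, 1L)
  expect_equal(dim(crops[[1]]), c(150L, 150L, 3L))
  # two participants are below the agreement threshold
  expect_length(cropMarkedRegions(img, marks[1:2, ]), 0L)
  # a centroid near the border clamps to the image bounds, size preserved
  edge <- data.frame(participant_id = c("a", "b", "c"),
                     x = c(8, 10, 12), y = c(190, 192, 194))
  crops <- cropMarkedRegions(img, edge)
  expect_equal(dim(crops[[1]]), c(150L, 150L, 3L))
  # two well-separated clusters give two crops
  two <- rbind(marks,
               data.frame(participant_id = c("d", "e", "f"),
                          x = c(450, 452, 455), y = c(60, 62, 58)))
  expect_length(cropMarkedRegions(img, two), 2L)
  expect_error(cropMarkedRegions(flatImage(100, 100), marks), "smaller")
  expect_error(
    cropMarkedRegions(img, data.frame(participant_id = "a", x = 600, y = 10)),
    "bounds")
})

test_that("lexicon counts conserve tokens and merge spelling variants", {
  ann <- data.frame(ssw = c("sara-sara", "sara-sara", "zara-zara"))
  lex <- buildLexicon(ann)
  expect_equal(nrow(lex), 2L)
  expect_equal(lex$count[lex$ssw == "sara-sara"], 2L)
  expect_equal(sum(lex$count), 3L)
  expect_equal(nrow(buildLexicon(data.frame(ssw = character()))), 0L)
  # hyphenated and doubled spellings collapse to one type
  lex2 <- buildLexicon(data.frame(ssw = c("gowagowa", "gowa-gowa")))
  expect_equal(nrow(lex2), 1L)
  expect_equal(lex2$count, 2L)
  expect_error(buildLexicon(data.frame(ssw = c("ok-ok", "puni"))), "row 1")
  expect_warning(
    lex3 <- buildLexicon(data.frame(ssw = c("qq!", "puni")),
                         skipUnparseable = TRUE), "skipping")
  expect_equal(lex3$ssw, "puni")
})

test_that("pair count equals token count and missing images fail", {
  images <- list(i1 = flatImage(8, 8), i2 = flatImage(8, 8),
                 i3 = flatImage(8, 8))
  ann <- data.frame(
    image_id = rep(c("i1", "i2"), each = 10),
    participant_id = rep(sprintf("p%02d", 1:10), 2),
    ssw = rep(c("puni", "zara-zara"), each = 10))
  ts <- makePairs(images, ann)
  expect_equal(nrow(ts@samples), 20L)
  expect_equal(nrow(ts@targets), 20L)
  expect_false("i3" %in% ts@samples$image_id)  # unannotated: zero pairs
  expect_identical(ts@targets[1, ], phonoBits(encodeSSW("puni")))
  bad <- ann; bad$image_id[1] <- "nope"
  expect_error(makePairs(images, bad), "missing image")
})

test_that("ten-fold bookkeeping matches the corpus-scale partition", {
  expect_equal(foldSizes(1946, 10), c(train = 1751L, test = 195L))
  ids <- sprintf("img%04d", 1:1946)
  fold <- assignFolds(ids, 10, seed = 3)
  expect_equal(sort(unique(fold)), 1:10)
  expect_equal(sum(lengths(split(ids, fold))), 1946L)
  expect_true(all(abs(table(fold) - 194.6) <= 0.6))
  expect_true(!anyDuplicated(unlist(split(ids, fold))))
  expect_error(assignFolds(ids[1:5], 10), "fewer images")
})

test_that("annotation and lexicon TSVs round-trip", {
  ann <- data.frame(
    image_id = c("i1", "i1", "i1", "i2"),
    participant_id = c("p1", "p1", "p2", "p1"),
    ssw = c("puni", "fuwa-fuwa", "zara-zara", "gowa-gowa"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeAnnotations(ann, tf)
  back <- readAnnotations(tf)
  expect_equal(nrow(back), 4L)
  expect_setequal(back$ssw, ann$ssw)
  lex <- buildLexicon(back)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLexicon(lex, tf2)
  expect_equal(readLexicon(tf2), lex)
})
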