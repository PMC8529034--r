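test_that("texture generation is deterministic and shape-correct", {
  p <- textureParams(roughness = 0.7, seed = 21)
  img1 <- genTexture(p)
  img2 <- genTexture(p)
  expect_identical(img1, img2)
  expect_equal(dim(img1), c(150L, 150L, 3L))
  expect_true(all(img1 >= 0 & img1 <= 1))
  expect_equal(dim(genTexture(p, size = 64))[1:2], c(64L, 64L))
  expect_error(textureParams(roughness = 1.2), "\\[0,1\\]")
})

test_that("roughness raises high-frequency energy at a fixed seed", {
  highpass <- function(img) {
    g <- img[, , 1]
    mean((g - TextureSSW:::.gblur2d(g, 2))^2)
  }
  rough <- genTexture(textureParams(roughness = 0.9, seed = 33))
  smooth <- genTexture(textureParams(roughness = 0.1, seed = 33))
  expect_gt(highpass(rough), highpass(smooth))
})

test_that("simulated annotators answer one to six tokens each", {
  p <- textureParams(seed = 17)
  ann <- simulateAnnotations(p, annotators = 10, seed = 17)
  perAnnotator <- table(ann$participant_id)
  expect_length(perAnnotator, 10L)
  expect_true(all(perAnnotator >= 1 & perAnnotator <= 6))
  expect_gte(nrow(ann), 10L)
  expect_lte(nrow(ann), 60L)
  expect_equal(nrow(simulateAnnotations(p, annotators = 0)), 0L)
  # every sampled token is parseable
  expect_silent(invisible(canonicalSSW(ann$ssw)))
})

test_that("planted voicing association shows up in token statistics", {
  rules <- defaultAssociationRules()
  voicedFraction <- function(roughness, seed) {
    p <- textureParams(roughness = roughness, glossiness = 0.5,
                       softness = 0.5, wetness = 0.5, granularity = 0.5,
                       seed = seed)
    ann <- simulateAnnotations(p, rules, annotators = 250, seed = seed)
    forms <- lapply(ann$ssw, parseSSW)
    voiced <- c("g", "gy", "z", "zy", "d", "dy", "b", "by")
    mean(vapply(forms, function(f) f@consonant1 %in% voiced, logical(1)))
  }
  expect_gt(voicedFraction(0.95, 71), voicedFraction(0.05, 72))
  expect_gt(voicedFraction(0.95, 71), 0.5)
  expect_lt(voicedFraction(0.05, 72), 0.2)
})

test_that("corpus generation is reproducible and interface-compatible", {
  c1 <- genCorpus(5, seed = 88)
  c2 <- genCorpus(5, seed = 88)
  expect_identical(corpusImages(c1), corpusImages(c2))
  expect_identical(corpusAnnotations(c1), corpusAnnotations(c2))
  n <- nrow(corpusAnnotations(c1))
  expect_gte(n, 10 * 5); expect_lte(n, 60 * 5)
  lex <- buildLexicon(corpusAnnotations(c1))
  expect_gt(nrow(lex), 0)
  expect_equal(sum(lex$count), n)
})

test_that("a corpus directory round-trips through the TSV/PNG formats", {
  corpus <- genCorpus(3, seed = 91)
  dir <- withr::local_tempdir()
  writeCorpus(corpus, dir)
  expect_true(file.exists(file.path(dir, "annotations.tsv")))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  back <- readCorpus(dir)
  expect_equal(names(corpusImages(back)), names(corpusImages(corpus)))
  # 8-bit PNG quantization keeps pixels within half a level
  expect_lt(max(abs(corpusImages(back)[[1]] - corpusImages(corpus)[[1]])),
            1 / 255)
  expect_equal(sort(corpusAnnotations(back)$ssw),
               sort(corpusAnnotations(corpus)$ssw))
  lex <- buildLexicon(readAnnotations(file.path(dir, "annotations.tsv")))
  expect_equal(sum(lex$count), nrow(corpusAnnotations(corpus)))
})
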