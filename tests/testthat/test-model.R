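smallTestConfig <- function(...) smallModelConfig(seed = 5, ...)

# tiny in-memory corpus reused across blocks
makeTinyCorpus <- function(n = 12, seed = 99) genCorpus(n, seed = seed)

test_that("models output 88 values with valid probabilities", {
  m <- buildModel(smallTestConfig())
  img <- genTexture(textureParams(seed = 2))
  pred <- predictPhonemes(m, img)
  expect_length(pred$output, 88L)
  expect_true(all(is.finite(pred$output)))
  p <- probVector(pred$probabilities)
  lay <- phonoLayout()
  off <- cumsum(c(0, lay))
  for (g in c("v1", "c1", "v2", "c2")) {
    i <- match(g, names(lay))
    expect_equal(sum(p[(off[i] + 1):off[i + 1]]), 1, tolerance = 1e-6)
  }
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the full-scale backbone profile also ends in 88 outputs", {
  m <- buildModel(modelConfig(backbone = "vgg16"))
  expect_equal(nrow(m@fc[[length(m@fc)]]$W), 88L)
  expect_length(m@conv, 13L)
  expect_length(m@fc, 3L)
  cfg <- modelConfig()
  expect_equal(cfg$batchSize, 40L)
  expect_equal(cfg$momentum, 0.5)
  expect_equal(cfg$learningRate, 2.5e-6)
  expect_equal(cfg$epochs, 100L)
  expect_equal(cfg$dropout, 0.5)
  expect_true(cfg$freezeConv)
})

test_that("composite loss agrees with scoreCandidate and the oracle", {
  set.seed(53)
  for (i in 1:100) {
    w <- renderSSW(randomForm())
    out <- randomOutput()
    v <- encodeSSW(w)
    expect_equal(compositeLoss(out, v), scoreCandidate(out, w),
                 tolerance = 1e-9)
    expect_equal(compositeLoss(out, v), oracleLoss(out, phonoBits(v)),
                 tolerance = 1e-9)
  }
})

test_that("composite loss is additive over blocks and a mean over batches", {
  set.seed(59)
  out <- randomOutput()
  bits <- phonoBits(encodeSSW("zara-zara"))
  lay <- phonoLayout()
  off <- cumsum(c(0, lay))
  perGroup <- 0
  for (i in seq_along(lay)) {
    idx <- (off[i] + 1):off[i + 1]
    # score each block in isolation by saturating every other block
    iso <- 50 * (2 * as.numeric(bits) - 1)
    iso[idx] <- out[idx]
    perGroup <- perGroup + compositeLoss(iso, bits)
  }
  expect_equal(perGroup, compositeLoss(out, bits), tolerance = 1e-6)
  O <- rbind(out, randomOutput(), randomOutput())
  T <- rbind(bits, phonoBits(encodeSSW("puni")), phonoBits(encodeSSW("fuwa-fuwa")))
  expect_equal(compositeLoss(O, T),
               mean(sapply(1:3, function(i) compositeLoss(O[i, ], T[i, ]))),
               tolerance = 1e-9)
})

test_that("training decreases loss, freezes the backbone, and is reproducible", {
  corpus <- makeTinyCorpus()
  ts <- makePairs(corpusImages(corpus), corpusAnnotations(corpus))
  cfg <- smallTestConfig(epochs = 5L)
  fit1 <- trainModel(ts, cfg)
  cv <- fitCurve(fit1)
  expect_equal(nrow(cv), 5L)
  expect_lt(cv$train_loss[5], cv$train_loss[1])
  # frozen backbone: conv weights identical to a freshly built model
  fresh <- buildModel(cfg)
  for (i in seq_along(fresh@conv))
    expect_identical(fitModel(fit1)@conv[[i]]$W, fresh@conv[[i]]$W)
  # and FC weights did change
  expect_gt(max(abs(fitModel(fit1)@fc[[1]]$W - fresh@fc[[1]]$W)), 0)
  fit2 <- trainModel(ts, cfg)
  expect_identical(fitCurve(fit1), fitCurve(fit2))
  expect_equal(fitModel(fit1)@fc[[3]]$W, fitModel(fit2)@fc[[3]]$W)
  expect_error(trainModel(ts, smallTestConfig(freezeConv = FALSE)),
               "frozen")
})

test_that("held-out images never contribute to training", {
  corpus <- makeTinyCorpus()
  ts <- makePairs(corpusImages(corpus), corpusAnnotations(corpus))
  ids <- names(corpusImages(corpus))
  fit <- trainModel(ts, smallTestConfig(epochs = 2L),
                    testImages = ids[1:3])
  expect_identical(fitTestImages(fit), ids[1:3])
  expect_false(any(is.na(fitCurve(fit)$test_loss)))
})
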