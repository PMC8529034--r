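## Convolutional backbone + fully connected head. The training regime of
## the reference system freezes all convolutional layers, so the backbone
## acts as a fixed (seeded random-filter) feature extractor and gradient
## descent updates only the FC head.

#' Model configuration
#'
#' Defaults mirror the full-scale training regime: VGG16-style backbone
#' (13 convolutional + 3 fully connected layers), frozen convolutional
#' weights, dropout 0.5 on the first two FC layers, SGD with batch size
#' 40, momentum 0.5, learning rate 2.5e-6, 100 epochs.
#'
#' @param backbone \code{"vgg16"} (13 conv + 3 FC, 224 px input) or
#'   \code{"small"} (3 conv stages + 3 FC, 64 px input) — the desk-scale
#'   profile used throughout the tests and the synthetic experiments.
#' @param freezeConv Keep convolutional weights fixed during training.
#' @param dropout Dropout rate on the first two FC layers.
#' @param batchSize Mini-batch size.
#' @param momentum SGD momentum factor.
#' @param learningRate SGD learning rate.
#' @param epochs Training epochs.
#' @param seed Seed fixing initialization, dropout and batch order.
#' @return Configuration list.
#' @export
modelConfig <- function(backbone = c("vgg16", "small"), freezeConv = TRUE,
                        dropout = 0.5, batchSize = 40L, momentum = 0.5,
                        learningRate = 2.5e-6, epochs = 100L, seed = 1L) {
  backbone <- match.arg(backbone)
  list(backbone = backbone, freezeConv = freezeConv, dropout = dropout,
       batchSize = as.integer(batchSize), momentum = momentum,
       learningRate = learningRate, epochs = as.integer(epochs),
       seed = as.integer(seed))
}

#' @rdname modelConfig
#' @param ... Overrides passed to [modelConfig()].
#' @details \code{smallModelConfig()} is the desk-scale profile: the small
#'   backbone with a learning rate of 0.01 and 10 epochs, suited to
#'   corpora of a few hundred images where only the FC head is trained.
#' @export
smallModelConfig <- function(...) {
  cfg <- modelConfig(backbone = "small", learningRate = 0.01,
                     epochs = 10L)
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

## Architecture tables: conv stages as (in, out, pool) with 3x3 filters.
.architecture <- function(backbone) {
  switch(backbone,
    vgg16 = list(
      input = 224L,
      conv = list(
        c(3L, 64L, 1L), c(64L, 64L, 2L),
        c(64L, 128L, 1L), c(128L, 128L, 2L),
        c(128L, 256L, 1L), c(256L, 256L, 1L), c(256L, 256L, 2L),
        c(256L, 512L, 1L), c(512L, 512L, 1L), c(512L, 512L, 2L),
        c(512L, 512L, 1L), c(512L, 512L, 1L), c(512L, 512L, 2L)),
      fc = c(4096L, 4096L, 88L)),
    small = list(
      input = 64L,
      conv = list(c(3L, 16L, 2L), c(16L, 32L, 2L), c(32L, 64L, 2L)),
      pooling = "stats",
      fc = c(64L, 64L, 88L)),
    stop("unknown backbone: ", backbone, call. = FALSE)
  )
}

#' Build a model
#'
#' Initializes He-scaled random convolution filters and FC weights from
#' \code{config$seed}. The final FC layer has 88 outputs, one per entry of
#' the phonological code.
#'
#' @param config A list from [modelConfig()] or [smallModelConfig()].
#' @return An \linkS4class{SSWModel}.
#' @examples
#' m <- buildModel(smallModelConfig())
#' length(predictPhonemes(m, genTexture(textureParams(seed = 1)))$output)
#' @export
buildModel <- function(config = modelConfig()) {
  arch <- .architecture(config$backbone)
  .withSeed(config$seed, {
    conv <- lapply(arch$conv, function(sp) {
      fanIn <- 9L * sp[1]
      list(
        ## filters: (3*3*in) x out matrix applied to im2col patches
        W = matrix(stats::rnorm(fanIn * sp[2], sd = sqrt(2 / fanIn)),
                   nrow = fanIn, ncol = sp[2]),
        b = numeric(sp[2]),
        pool = sp[3]
      )
    })
    pooling <- if (is.null(arch$pooling)) "flatten" else arch$pooling
    if (pooling == "stats") {
      ## translation-invariant texture statistics: per-channel mean and sd
      ## of every stage's rectified responses
      featureDim <- as.integer(2L * sum(vapply(arch$conv, `[`, 0L, 2L)))
    } else {
      side <- arch$input
      for (sp in arch$conv) side <- (side - 2L) %/% sp[3]
      featureDim <- as.integer(side^2 * arch$conv[[length(arch$conv)]][2])
    }
    dims <- c(featureDim, arch$fc)
    fc <- lapply(seq_along(arch$fc), function(i) {
      list(W = matrix(stats::rnorm(dims[i + 1] * dims[i],
                                   sd = sqrt(2 / dims[i])),
                      nrow = dims[i + 1], ncol = dims[i]),
           b = numeric(dims[i + 1]))
    })
    config$pooling <- pooling
    new("SSWModel", config = config, conv = conv, fc = fc,
        inputSize = arch$input, featureDim = featureDim,
        featCenter = numeric(featureDim),
        featScale = rep(1, featureDim))
  })
}

## Run expr with a temporary RNG state seeded by `seed`.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

## Fixed channel standardization constants (RGB means / sds commonly used
## for natural-image backbones).
.CHANNEL_MEAN <- c(0.485, 0.456, 0.406)
.CHANNEL_SD <- c(0.229, 0.224, 0.225)

## Resize (bilinear) to the backbone's native input and standardize.
.preprocess <- function(img, inputSize) {
  stopifnot(is.array(img), length(dim(img)) == 3L, dim(img)[3] == 3L)
  if (dim(img)[1] != inputSize || dim(img)[2] != inputSize) {
    img <- EBImage::resize(EBImage::Image(img, colormode = "Color"),
                           w = inputSize, h = inputSize)
    img <- array(EBImage::imageData(img), dim = c(inputSize, inputSize, 3L))
  }
  for (ch in 1:3)
    img[, , ch] <- (img[, , ch] - .CHANNEL_MEAN[ch]) / .CHANNEL_SD[ch]
  img
}

## im2col for 3x3 valid convolution: returns (outH*outW) x (9*channels).
.im2col3 <- function(x) {
  d <- dim(x)
  outH <- d[1] - 2L; outW <- d[2] - 2L
  cols <- matrix(0, outH * outW, 9L * d[3])
  k <- 0L
  for (ch in seq_len(d[3])) for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    cols[, k] <- as.vector(x[di + seq_len(outH), dj + seq_len(outW), ch])
  }
  cols
}

.maxPool <- function(x, p) {
  if (p <= 1L) return(x)
  d <- dim(x)
  oh <- d[1] %/% p; ow <- d[2] %/% p
  out <- array(-Inf, c(oh, ow, d[3]))
  for (di in seq_len(p)) for (dj in seq_len(p)) {
    out <- pmax(out, x[seq(di, by = p, length.out = oh),
                       seq(dj, by = p, length.out = ow), , drop = FALSE])
  }
  out
}

## Frozen conv forward: image array -> feature vector of length featureDim.
## "stats" pooling summarizes each stage by per-channel mean and sd of the
## rectified responses (translation-invariant texture energies); "flatten"
## keeps the final spatial map.
.convFeatures <- function(model, img) {
  stats <- identical(model@config$pooling, "stats")
  x <- .preprocess(img, model@inputSize)
  feats <- list()
  for (layer in model@conv) {
    d <- dim(x)
    z <- .im2col3(x) %*% layer$W
    z <- sweep(z, 2, layer$b, "+")
    z[z < 0] <- 0
    if (stats) feats[[length(feats) + 1L]] <-
      c(colMeans(z), apply(z, 2, stats::sd))
    x <- array(z, c(d[1] - 2L, d[2] - 2L, ncol(layer$W)))
    x <- .maxPool(x, layer$pool)
  }
  if (stats) unlist(feats) else as.vector(x)
}

## Feature matrix for a named list of images (rows = image ids). Cached per
## call site; conv weights are frozen so features never change during
## training.
.featureMatrix <- function(model, images) {
  feats <- t(vapply(images, function(im) .convFeatures(model, im),
                    numeric(model@featureDim)))
  rownames(feats) <- names(images)
  feats
}

## FC head forward. X: n x featureDim. Returns list of activations and the
## raw n x 88 output. Dropout (inverted scaling) on the first two layers
## when training.
.fcForward <- function(fc, X, dropout = 0, training = FALSE) {
  a <- list(X)
  masks <- list()
  H <- X
  for (i in seq_along(fc)) {
    Z <- H %*% t(fc[[i]]$W)
    Z <- sweep(Z, 2, fc[[i]]$b, "+")
    if (i < length(fc)) {
      Z[Z < 0] <- 0
      if (training && dropout > 0 && i <= 2L) {
        mask <- matrix(stats::runif(length(Z)) >= dropout,
                       nrow(Z), ncol(Z)) / (1 - dropout)
        Z <- Z * mask
        masks[[i]] <- mask
      }
    }
    H <- Z
    a[[i + 1L]] <- H
  }
  list(activations = a, output = H, masks = masks)
}

#' Composite softmax/sigmoid cross-entropy loss
#'
#' Loss of raw 88-dimensional outputs against binary phonological targets:
#' log-softmax cross-entropy over the one-hot blocks (v1, c1, v2, c2) plus
#' log-sigmoid (binary) cross-entropy over the special, repetition and
#' hash entries; the block losses add because the blocks are independent
#' predictors. For a batch the loss is the mean over samples of the
#' per-sample sum, and it equals [scoreCandidate()] on a single pair.
#'
#' @param output Numeric vector of 88 raw values, or an n x 88 matrix.
#' @param target A \linkS4class{PhonoVector}, an 88-bit vector, or an
#'   n x 88 matrix of bits matching \code{output}.
#' @return Scalar loss.
#' @export
compositeLoss <- function(output, target) {
  if (is(target, "PhonoVector")) target <- phonoBits(target)
  O <- if (is.null(dim(output))) matrix(output, nrow = 1) else output
  T <- if (is.null(dim(target))) matrix(target, nrow = 1) else target
  stopifnot(nrow(O) == nrow(T), ncol(O) == 88L, ncol(T) == 88L)
  sigIdx <- unlist(lapply(.SIGMOID_GROUPS, .groupIndex))
  perSample <- rowSums(.softplus(O[, sigIdx, drop = FALSE])) -
    rowSums(O * T)
  for (g in .SOFTMAX_GROUPS)
    perSample <- perSample + .rowLogSumExp(O[, .groupIndex(g), drop = FALSE])
  mean(perSample)
}

## Gradient of the composite loss wrt raw outputs: uniformly
## probabilities - targets (softmax within one-hot blocks, sigmoid
## elsewhere), scaled by 1/n for the batch mean.
.outputGradient <- function(O, T) {
  P <- O
  for (g in .SOFTMAX_GROUPS) {
    idx <- .groupIndex(g)
    Z <- O[, idx, drop = FALSE]
    Z <- exp(Z - apply(Z, 1, max))
    P[, idx] <- Z / rowSums(Z)
  }
  sigIdx <- unlist(lapply(.SIGMOID_GROUPS, .groupIndex))
  P[, sigIdx] <- stats::plogis(O[, sigIdx, drop = FALSE])
  (P - T) / nrow(O)
}

#' Train a model on image/phonological-vector pairs
#'
#' Stochastic gradient descent with momentum on the FC head; the
#' convolutional backbone stays frozen (the reference regime), so image
#' features are extracted once and reused across epochs. One training pair
#' per annotated token: an image annotated k times contributes k pairs.
#' Images listed in \code{testImages} are excluded from training and their
#' pairs form the held-out loss; fold assembly always splits by image id so
#' no image spans train and test.
#'
#' @param trainingSet An \linkS4class{SSWTrainingSet} from [makePairs()].
#' @param config Configuration from [modelConfig()]/[smallModelConfig()].
#' @param testImages Character ids of held-out images (may be empty).
#' @param trackAccuracy Optional list with elements \code{lexicon} (passed
#'   to [rankCandidates()]) and \code{answered} (named list of answered
#'   SSW sets per image): records held-out rank-1/rank-2 accuracy per
#'   epoch in the learning curve.
#' @return An \linkS4class{SSWFit}.
#' @seealso [crossValidate()] for the k-fold wrapper.
#' @export
trainModel <- function(trainingSet, config = smallModelConfig(),
                       testImages = character(), trackAccuracy = NULL) {
  stopifnot(is(trainingSet, "SSWTrainingSet"))
  if (!isTRUE(config$freezeConv))
    stop("only the frozen-backbone regime is supported: set freezeConv = TRUE",
         call. = FALSE)
  if (!nrow(trainingSet@samples)) stop("no training pairs", call. = FALSE)
  model <- buildModel(config)
  feats <- .featureMatrix(model, trainingSet@images)
  ids <- trainingSet@samples$image_id
  ## standardize features on the training images only, then apply everywhere
  trainIds <- setdiff(names(trainingSet@images), testImages)
  ctr <- colMeans(feats[trainIds, , drop = FALSE])
  scl <- apply(feats[trainIds, , drop = FALSE], 2, stats::sd)
  scl[scl < 1e-8] <- 1
  model@featCenter <- ctr
  model@featScale <- scl
  feats <- sweep(sweep(feats, 2, ctr), 2, scl, "/")
  isTest <- ids %in% testImages
  Xtr <- feats[ids[!isTest], , drop = FALSE]
  Ttr <- trainingSet@targets[!isTest, , drop = FALSE]
  Xte <- feats[ids[isTest], , drop = FALSE]
  Tte <- trainingSet@targets[isTest, , drop = FALSE]
  if (!nrow(Xtr)) stop("no training pairs left after holdout", call. = FALSE)

  fc <- model@fc
  vel <- lapply(fc, function(l) list(W = 0 * l$W, b = 0 * l$b))
  n <- nrow(Xtr)
  curve <- data.frame(epoch = seq_len(config$epochs),
                      train_loss = NA_real_, test_loss = NA_real_,
                      acc1 = NA_real_, acc2 = NA_real_)
  .withSeed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batchSize)
      for (s in starts) {
        take <- perm[s:min(s + config$batchSize - 1L, n)]
        fw <- .fcForward(fc, Xtr[take, , drop = FALSE],
                         dropout = config$dropout, training = TRUE)
        dZ <- .outputGradient(fw$output, Ttr[take, , drop = FALSE])
        for (i in rev(seq_along(fc))) {
          A <- fw$activations[[i]]
          gW <- t(dZ) %*% A
          gb <- colSums(dZ)
          if (i > 1L) {
            dZ <- dZ %*% fc[[i]]$W
            if (length(fw$masks) >= i - 1L && !is.null(fw$masks[[i - 1L]]))
              dZ <- dZ * fw$masks[[i - 1L]]
            dZ[fw$activations[[i]] <= 0] <- 0
          }
          vel[[i]]$W <- config$momentum * vel[[i]]$W - config$learningRate * gW
          vel[[i]]$b <- config$momentum * vel[[i]]$b - config$learningRate * gb
          fc[[i]]$W <- fc[[i]]$W + vel[[i]]$W
          fc[[i]]$b <- fc[[i]]$b + vel[[i]]$b
        }
      }
      curve$train_loss[epoch] <-
        compositeLoss(.fcForward(fc, Xtr)$output, Ttr)
      if (nrow(Xte))
        curve$test_loss[epoch] <-
          compositeLoss(.fcForward(fc, Xte)$output, Tte)
      if (!is.null(trackAccuracy) && length(testImages)) {
        outs <- .fcForward(fc, feats[testImages, , drop = FALSE])$output
        rownames(outs) <- testImages
        acc <- .rankAccuracy(outs, trackAccuracy$lexicon,
                             trackAccuracy$answered, ranks = 2L)
        curve$acc1[epoch] <- acc[1]
        curve$acc2[epoch] <- acc[2]
      }
    }
  })
  model@fc <- fc
  new("SSWFit", model = model, curve = curve,
      testImages = as.character(testImages))
}

#' k-fold cross-validation by image id
#'
#' Partitions image ids into \code{folds} disjoint folds with
#' [assignFolds()] and trains one model per fold with that fold held out.
#'
#' @inheritParams trainModel
#' @param folds Number of folds (must not exceed the number of images).
#' @return List of \linkS4class{SSWFit}, one per fold.
#' @export
crossValidate <- function(trainingSet, config = smallModelConfig(),
                          folds = 10L, trackAccuracy = NULL) {
  ids <- names(trainingSet@images)
  if (length(ids) < folds)
    stop("fewer images (", length(ids), ") than folds (", folds, ")",
         call. = FALSE)
  fold <- assignFolds(ids, folds, seed = config$seed)
  lapply(seq_len(folds), function(k) {
    trainModel(trainingSet, config, testImages = ids[fold == k],
               trackAccuracy = trackAccuracy)
  })
}

#' Predict raw output and probabilities for images
#'
#' @param model An \linkS4class{SSWModel} or \linkS4class{SSWFit}.
#' @param image A single H x W x 3 array, or a named list of them.
#' @return For a single image, a list with \code{output} (raw numeric 88)
#'   and \code{probabilities} (\linkS4class{GroupProbabilities}); for a
#'   list, the n x 88 raw output matrix (rows named by image id).
#' @export
predictPhonemes <- function(model, image) {
  if (is(model, "SSWFit")) model <- model@model
  stopifnot(is(model, "SSWModel"))
  single <- is.array(image)
  images <- if (single) list(img = image) else image
  feats <- .featureMatrix(model, images)
  feats <- sweep(sweep(feats, 2, model@featCenter), 2, model@featScale, "/")
  out <- .fcForward(model@fc, feats)$output
  rownames(out) <- names(images)
  if (single) {
    o <- drop(out)
    names(o) <- .phonoNames()
    list(output = o, probabilities = normalizeOutput(o))
  } else out
}
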