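## Procedural texture corpus with sound-symbolically consistent simulated
## annotators. Latent perceptual parameters drive both the image synthesis
## and the phoneme distributions the annotators sample from, so parameter
## recovery is testable end to end.

#' Latent texture parameters
#'
#' Perceptual dimensions in [0,1] driving both image synthesis and
#' annotator simulation, plus the seed that fixes them jointly.
#'
#' @param roughness High-frequency noise amplitude.
#' @param glossiness Density of specular-like bright spots.
#' @param softness Blur of the surface structure (and soft-feel phonology).
#' @param wetness Dark/cool tint (and wet-feel phonology).
#' @param granularity Spatial scale of the base noise.
#' @param seed Integer seed.
#' @return Named list of class parameters.
#' @export
textureParams <- function(roughness = 0.5, glossiness = 0.5,
                          softness = 0.5, wetness = 0.5,
                          granularity = 0.5, seed = 1L) {
  p <- list(roughness = roughness, glossiness = glossiness,
            softness = softness, wetness = wetness,
            granularity = granularity, seed = as.integer(seed))
  num <- unlist(p[1:5])
  if (any(num < 0 | num > 1))
    stop("texture parameters must lie in [0,1]", call. = FALSE)
  p
}

.gblur2d <- function(m, sigma) {
  out <- EBImage::gblur(EBImage::Image(m), sigma = sigma)
  matrix(EBImage::imageData(out), nrow(m), ncol(m))
}

#' Generate a procedural texture image
#'
#' Deterministic per seed. A band-limited value-noise base (cell size set
#' by granularity) is overlaid with white noise scaled by roughness,
#' blurred in proportion to softness, decorated with Gaussian specular
#' spots in proportion to glossiness, and tinted darker/cooler with
#' wetness.
#'
#' @param params A [textureParams()] list.
#' @param size Square output edge in pixels (the 150-px crop convention).
#' @return \code{size} x \code{size} x 3 array in [0,1].
#' @examples
#' img <- genTexture(textureParams(roughness = 0.9, seed = 7))
#' dim(img)
#' @export
genTexture <- function(params, size = 150L) {
  size <- as.integer(size)
  .withSeed(params$seed, {
    cell <- 4L + as.integer(round(params$granularity * 20))
    g <- ceiling(size / cell) + 1L
    grid <- matrix(stats::rnorm(g * g), g, g)
    up <- EBImage::resize(EBImage::Image(grid), w = size, h = size)
    base <- 0.5 + 0.18 * matrix(EBImage::imageData(up), size, size)
    base <- base + params$roughness * 0.22 *
      matrix(stats::rnorm(size * size), size, size)
    sigma <- params$softness * 1.5
    if (sigma > 0.05) base <- .gblur2d(base, sigma)
    nspots <- round(params$glossiness * 15)
    if (nspots > 0) {
      rows <- matrix(seq_len(size), size, size)
      cols <- t(rows)
      for (s in seq_len(nspots)) {
        cy <- stats::runif(1, 1, size); cx <- stats::runif(1, 1, size)
        rad <- stats::runif(1, 3, 8)
        base <- base + 0.35 * exp(-((rows - cy)^2 + (cols - cx)^2) /
                                    (2 * rad^2))
      }
    }
    base <- pmin(pmax(base, 0), 1)
    tint <- c(
      (1 - 0.25 * params$wetness) * (1 + 0.06 * params$softness),
      1 - 0.10 * params$wetness,
      1 + 0.08 * params$wetness
    )
    img <- array(0, c(size, size, 3L))
    for (ch in 1:3) img[, , ch] <- pmin(pmax(base * tint[ch], 0), 1)
    img
  })
}

#' Association rules linking texture parameters to phoneme weights
#'
#' Coefficient matrices mapping \code{(1, roughness, glossiness, softness,
#' wetness, granularity)} to log-weights per slot element. The defaults
#' encode the documented sound-symbolic associations: voiced consonants
#' rise with roughness and voiceless ones with smoothness; /u/ rises with
#' softness while /i/ and /e/ track negative (rough or wet) feel and
#' /o/, /a/ rough, hard, dry feel; bilabial plosives /p/, /b/ and the
#' nasal /n/ follow soft, sticky, wet textures; the /k/ and /t/ rows follow
#' hard, slippery, dry ones. Special-phoneme and repetition entries are
#' Bernoulli logits.
#'
#' @param sharpness Temperature applied to the categorical (vowel and
#'   consonant) log-weights. The default concentrates per-image word
#'   distributions so that a simulated corpus reproduces the reference
#'   corpus statistics (on the order of 15 tokens per lexicon type, with
#'   a few words dominating each image's answers) instead of a
#'   near-uniform draw over the phoneme space.
#' @return List of coefficient matrices \code{vowel} (5 x 6),
#'   \code{consonant} (27 x 6), \code{specials1} (3 x 6), \code{specials2}
#'   (4 x 6) and \code{repetition} (1 x 6); columns are the intercept and
#'   the five texture dimensions.
#' @export
defaultAssociationRules <- function(sharpness = 2.5) {
  cols <- c("intercept", "roughness", "glossiness", "softness", "wetness",
            "granularity")
  mk <- function(symbols) {
    m <- matrix(0, length(symbols), length(cols),
                dimnames = list(symbols, cols))
    m
  }
  ## Weight scale is calibrated so the sampled corpus matches the reference
  ## corpus statistics (roughly 15 tokens per lexicon type, a few dominant
  ## words per image), not a near-uniform draw over the phoneme space.
  vowel <- mk(.VOWELS)
  vowel[, "intercept"] <- c(a = 0.5, i = 0, u = 0, e = -1, o = 0.3)
  vowel[c("a", "o"), c("roughness", "softness", "wetness")] <-
    rep(c(2.5, -1.5, -1.5), each = 2)
  vowel[c("i", "e"), c("roughness", "wetness")] <- 1.0
  vowel["u", "softness"] <- 2.5
  consonant <- mk(.CONSONANTS)
  palatal <- grep("y$", .CONSONANTS, value = TRUE)
  consonant[palatal, "intercept"] <- -2.5   # palatalized onsets are rare
  consonant[.VOICED_CONSONANTS, "roughness"] <- 5.0
  consonant[.VOICELESS_CONSONANTS, "intercept"] <-
    consonant[.VOICELESS_CONSONANTS, "intercept"] + 5.0
  consonant[.VOICELESS_CONSONANTS, "roughness"] <- -5.0
  ## within-category base preferences (common vs rare onsets)
  pref <- c(g = 1.2, z = 0.8, b = 0.4, d = 0,
            s = 1.2, k = 0.9, t = 0.6, h = 0.3, p = 0,
            m = 0.5, n = 0.3, r = 0.8, w = 0.6, y = -0.5)
  consonant[names(pref), "intercept"] <-
    consonant[names(pref), "intercept"] + pref
  soft_wet <- c("p", "b", "n")
  consonant[soft_wet, "softness"] <- consonant[soft_wet, "softness"] + 1.5
  consonant[soft_wet, "wetness"] <- consonant[soft_wet, "wetness"] + 1.5
  hard_dry <- c("k", "ky", "t", "ty")
  consonant[hard_dry, "softness"] <- consonant[hard_dry, "softness"] - 1.5
  consonant[hard_dry, "wetness"] <- consonant[hard_dry, "wetness"] - 1.5
  consonant[hard_dry, "glossiness"] <- 1.0
  consonant[match("", .CONSONANTS), "intercept"] <- -2.0  # onsetless mora
  specials1 <- mk(.SPECIALS1)
  specials1["N", c("intercept", "wetness")] <- c(-3.0, 1.5)
  specials1["Q", c("intercept", "softness")] <- c(-1.5, -2.0)
  specials1["R", c("intercept", "softness")] <- c(-3.0, 1.5)
  specials2 <- mk(.SPECIALS2)
  specials2["N", c("intercept", "wetness")] <- c(-3.0, 1.5)
  specials2["Q", c("intercept", "softness")] <- c(-1.5, -2.0)
  specials2["R", c("intercept", "softness")] <- c(-3.0, 1.5)
  specials2["Li", "intercept"] <- -3.5
  repetition <- matrix(c(2.0, 0, 0, 0, 0.5, 0), 1,
                       dimnames = list("r", cols))
  list(vowel = sharpness * vowel, consonant = sharpness * consonant,
       specials1 = specials1, specials2 = specials2,
       repetition = repetition)
}

.ruleLogits <- function(M, params) {
  drop(M %*% c(1, params$roughness, params$glossiness, params$softness,
               params$wetness, params$granularity))
}

.sampleCategorical <- function(logits) {
  p <- exp(logits - max(logits))
  sample(names(logits), 1L, prob = p / sum(p))
}

## One sampled SSWForm under the rule-induced slot distributions
## (slot-independent sampling; correlations enter only through the rules).
.sampleForm <- function(params, rules) {
  vl <- .ruleLogits(rules$vowel, params)
  cl <- .ruleLogits(rules$consonant, params)
  cl2 <- cl
  # the second mora keeps an onset so the romaji stays unambiguous
  cl2[match("", .CONSONANTS)] <- -Inf
  s1p <- stats::plogis(.ruleLogits(rules$specials1, params))
  s2p <- stats::plogis(.ruleLogits(rules$specials2, params))
  rp <- stats::plogis(.ruleLogits(rules$repetition, params))
  SSWForm(
    consonant1 = .sampleCategorical(cl), vowel1 = .sampleCategorical(vl),
    specials1 = .SPECIALS1[stats::runif(3) < s1p],
    consonant2 = .sampleCategorical(cl2), vowel2 = .sampleCategorical(vl),
    specials2 = .SPECIALS2[stats::runif(4) < s2p],
    repetition = stats::runif(1) < rp
  )
}

#' Simulate annotators describing one texture
#'
#' Each simulated annotator answers one to six SSW tokens, sampling every
#' slot independently from the rule-induced distribution given the texture
#' parameters (the design the human experiment mirrors: 10 annotators per
#' image, one to six words each).
#'
#' @param params [textureParams()] of the texture being described.
#' @param rules Association rules, by default [defaultAssociationRules()].
#' @param annotators Number of simulated annotators.
#' @param seed Seed for the simulation.
#' @return Long data frame \code{participant_id}, \code{ssw}; between
#'   \code{annotators} and \code{6 * annotators} rows.
#' @export
simulateAnnotations <- function(params, rules = defaultAssociationRules(),
                                annotators = 10L, seed = params$seed) {
  if (annotators < 1L)
    return(data.frame(participant_id = character(), ssw = character(),
                      stringsAsFactors = FALSE))
  .withSeed(seed, {
    rows <- lapply(seq_len(annotators), function(a) {
      k <- sample.int(6L, 1L)
      data.frame(participant_id = sprintf("p%02d", a),
                 ssw = vapply(seq_len(k), function(i)
                   renderSSW(.sampleForm(params, rules)), character(1)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a full synthetic corpus
#'
#' Draws texture parameters uniformly, renders each image, and simulates
#' its annotations; ground-truth parameters are retained for recovery
#' tests. All randomness derives from \code{seed}.
#'
#' @param nImages Number of images.
#' @param seed Master seed.
#' @param annotators Annotators per image.
#' @param size Image edge in pixels.
#' @param rules Association rules.
#' @return A \linkS4class{TextureCorpus}.
#' @examples
#' corpus <- genCorpus(4, seed = 11)
#' corpus
#' @export
genCorpus <- function(nImages, seed = 1L, annotators = 10L, size = 150L,
                      rules = defaultAssociationRules()) {
  stopifnot(nImages >= 1L)
  spec <- .withSeed(seed, {
    data.frame(
      image_id = sprintf("img%04d", seq_len(nImages)),
      roughness = stats::runif(nImages), glossiness = stats::runif(nImages),
      softness = stats::runif(nImages), wetness = stats::runif(nImages),
      granularity = stats::runif(nImages),
      seed = sample.int(.Machine$integer.max - 1L, nImages),
      annot_seed = sample.int(.Machine$integer.max - 1L, nImages),
      stringsAsFactors = FALSE)
  })
  images <- list()
  annotations <- vector("list", nImages)
  for (i in seq_len(nImages)) {
    p <- textureParams(spec$roughness[i], spec$glossiness[i],
                       spec$softness[i], spec$wetness[i],
                       spec$granularity[i], spec$seed[i])
    images[[spec$image_id[i]]] <- genTexture(p, size = size)
    ann <- simulateAnnotations(p, rules, annotators,
                               seed = spec$annot_seed[i])
    if (nrow(ann)) ann <- cbind(image_id = spec$image_id[i], ann)
    annotations[[i]] <- ann
  }
  new("TextureCorpus", images = images,
      params = spec[, 1:7],
      annotations = do.call(rbind, annotations),
      seed = as.integer(seed))
}

#' Write / read a corpus directory
#'
#' Layout: one PNG per image, \code{annotations.tsv} (annotation format of
#' [readAnnotations()]) and \code{manifest.tsv} recording per-image seeds
#' and ground-truth texture parameters.
#'
#' @param corpus A \linkS4class{TextureCorpus}.
#' @param dir Directory (created if needed).
#' @return Invisibly, \code{dir}; \code{readCorpus()} returns the
#'   reconstructed \linkS4class{TextureCorpus}.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(corpus@images))
    png::writePNG(corpus@images[[id]], file.path(dir, paste0(id, ".png")))
  writeAnnotations(corpus@annotations, file.path(dir, "annotations.tsv"))
  utils::write.table(corpus@params, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCorpus
#' @export
readCorpus <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"), sep = "\t")
  images <- list()
  for (id in manifest$image_id) {
    a <- png::readPNG(file.path(dir, paste0(id, ".png")))
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
    images[[id]] <- a[, , 1:3, drop = FALSE]
  }
  new("TextureCorpus", images = images, params = manifest,
      annotations = readAnnotations(file.path(dir, "annotations.tsv")),
      seed = NA_integer_)
}

#' Total voiced-consonant probability mass of the first mora
#'
#' Sums the softmax probabilities of the voiced obstruent onsets
#' (/g/, /gy/, /z/, /zy/, /d/, /dy/, /b/, /by/) in the c1 block — the
#' quantity that should rise with perceived roughness.
#'
#' @param x A \linkS4class{GroupProbabilities} or a raw 88-dimensional
#'   output (vector or matrix of rows).
#' @return Numeric scalar, or one value per row for a matrix.
#' @export
voicedConsonantMass <- function(x) {
  if (is(x, "GroupProbabilities")) {
    p <- probGroup(x, "c1")
    return(sum(p[match(.VOICED_CONSONANTS, .CONSONANTS)]))
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  apply(x, 1, function(row)
    voicedConsonantMass(normalizeOutput(as.numeric(row))))
}
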