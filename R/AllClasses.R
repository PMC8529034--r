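#' @import methods
NULL

#' Two-mora structure of a sound-symbolic word
#'
#' Holds the parsed repetition unit of a Japanese sound-symbolic word (SSW):
#' consonant and vowel of each of the first two morae, the special phonemes
#' trailing each mora, the repetition flag, and the romanized surface text
#' the form was parsed from (or rendered to).
#'
#' @slot consonant1,consonant2 Consonant symbol per mora; \code{""} means
#'   the mora starts with a bare vowel.
#' @slot vowel1,vowel2 Vowel symbol per mora (always present).
#' @slot specials1 Subset of \code{sswSpecials1()} after mora 1.
#' @slot specials2 Subset of \code{sswSpecials2()} after mora 2.
#' @slot repetition Whether the unit is reduplicated ("gowa-gowa").
#' @slot surface The romanized source or canonical rendering.
#' @seealso [parseSSW()], [renderSSW()], [encodeSSW()]
#' @export
setClass("SSWForm", representation(
  consonant1 = "character", vowel1 = "character", specials1 = "character",
  consonant2 = "character", vowel2 = "character", specials2 = "character",
  repetition = "logical", surface = "character"
))

setValidity("SSWForm", function(object) {
  msg <- character()
  if (!(object@vowel1 %in% .VOWELS) || !(object@vowel2 %in% .VOWELS))
    msg <- c(msg, "vowels must belong to the vowel inventory")
  if (!(object@consonant1 %in% .CONSONANTS) ||
      !(object@consonant2 %in% .CONSONANTS))
    msg <- c(msg, "consonants must belong to the consonant inventory")
  if (!all(object@specials1 %in% .SPECIALS1))
    msg <- c(msg, "specials1 outside {N,Q,R}")
  if (!all(object@specials2 %in% .SPECIALS2))
    msg <- c(msg, "specials2 outside {N,Q,R,Li}")
  if (length(object@repetition) != 1L || is.na(object@repetition))
    msg <- c(msg, "repetition must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct an SSWForm
#'
#' @param consonant1,vowel1,specials1 First mora: onset (\code{""} for a bare
#'   vowel), vowel, and trailing special phonemes.
#' @param consonant2,vowel2,specials2 Second mora.
#' @param repetition Logical repetition flag.
#' @param surface Optional surface text; defaults to the canonical rendering.
#' @return An \linkS4class{SSWForm}.
#' @examples
#' SSWForm("g", "o", character(), "w", "a", character(), TRUE)
#' @export
SSWForm <- function(consonant1, vowel1, specials1 = character(),
                    consonant2, vowel2, specials2 = character(),
                    repetition = FALSE, surface = NA_character_) {
  obj <- new("SSWForm",
    consonant1 = consonant1, vowel1 = vowel1, specials1 = specials1,
    consonant2 = consonant2, vowel2 = vowel2, specials2 = specials2,
    repetition = repetition, surface = surface)
  if (is.na(obj@surface)) obj@surface <- renderSSW(obj)
  obj
}

setMethod("show", "SSWForm", function(object) {
  sp <- function(s) if (length(s)) paste0("+", paste(s, collapse = "+")) else ""
  cat(sprintf("SSWForm \"%s\": /%s%s/%s /%s%s/%s %s\n",
    renderSSW(object),
    object@consonant1, object@vowel1, sp(object@specials1),
    object@consonant2, object@vowel2, sp(object@specials2),
    if (object@repetition) "(repeated)" else "(single)"))
})

#' 88-dimensional binary phonological vector
#'
#' Binary code of an SSW: one-hot vowel and consonant blocks for the two
#' morae, multi-hot special-phoneme blocks, a repetition bit, and 16 hash
#' bits derived from the 72 preceding bits with MD5 (the correlation code).
#'
#' @slot bits Named integer vector of length 88 (0/1), layout per
#'   [phonoLayout()].
#' @seealso [encodeSSW()], [computeHashBits()]
#' @export
setClass("PhonoVector", representation(bits = "integer"))

setValidity("PhonoVector", function(object) {
  b <- object@bits
  msg <- character()
  if (length(b) != 88L) msg <- c(msg, "bits must have length 88")
  else {
    if (!all(b %in% c(0L, 1L))) msg <- c(msg, "bits must be 0/1")
    for (g in .SOFTMAX_GROUPS)
      if (sum(b[.groupIndex(g)]) != 1L)
        msg <- c(msg, paste0("block ", g, " must be one-hot"))
  }
  if (length(msg)) msg else TRUE
})

PhonoVector <- function(bits) {
  bits <- as.integer(bits)
  names(bits) <- .phonoNames()
  new("PhonoVector", bits = bits)
}

#' Extract the raw bits of a PhonoVector
#' @param x A \linkS4class{PhonoVector}.
#' @return Named integer vector of length 88.
#' @export
phonoBits <- function(x) {
  stopifnot(is(x, "PhonoVector"))
  x@bits
}

#' Extract one block of a PhonoVector
#' @param x A \linkS4class{PhonoVector}.
#' @param group Block name: one of \code{names(phonoLayout())}.
#' @return Integer sub-vector of the block.
#' @export
phonoGroup <- function(x, group) {
  stopifnot(is(x, "PhonoVector"))
  x@bits[.groupIndex(group)]
}

setMethod("show", "PhonoVector", function(object) {
  on <- names(object@bits)[object@bits == 1L]
  cat("PhonoVector (88 bits), set: ",
      paste(grep("^h", on, invert = TRUE, value = TRUE), collapse = " "),
      " + ", sum(object@bits[.groupIndex("h")]), " hash bits\n", sep = "")
})

#' Normalized per-group output probabilities
#'
#' The model's raw 88-dimensional output mapped to probabilities: softmax
#' within each one-hot block (v1, c1, v2, c2), elementwise sigmoid for the
#' special-phoneme, repetition and hash entries.
#'
#' @slot probs Named numeric vector of length 88 in [0,1]; softmax blocks
#'   sum to 1.
#' @seealso [normalizeOutput()], [decodeArgmax()]
#' @export
setClass("GroupProbabilities", representation(probs = "numeric"))

setValidity("GroupProbabilities", function(object) {
  p <- object@probs
  msg <- character()
  if (length(p) != 88L) msg <- c(msg, "probs must have length 88")
  else {
    if (any(p < -1e-9) || any(p > 1 + 1e-9))
      msg <- c(msg, "probabilities must lie in [0,1]")
    for (g in .SOFTMAX_GROUPS)
      if (abs(sum(p[.groupIndex(g)]) - 1) > 1e-6)
        msg <- c(msg, paste0("softmax block ", g, " must sum to 1"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct GroupProbabilities from per-block probabilities
#'
#' @param v1,c1,s1,v2,c2,s2,r,h Numeric blocks of lengths 5, 27, 3, 5, 27,
#'   4, 1, 16. \code{h} defaults to 0.5 (uninformative) if omitted.
#' @return A \linkS4class{GroupProbabilities}.
#' @export
groupProbabilities <- function(v1, c1, s1, v2, c2, s2, r,
                               h = rep(0.5, 16)) {
  p <- c(v1, c1, s1, v2, c2, s2, r, h)
  names(p) <- .phonoNames()
  new("GroupProbabilities", probs = p)
}

#' Extract probabilities
#' @param x A \linkS4class{GroupProbabilities}.
#' @return Named numeric vector of length 88.
#' @export
probVector <- function(x) {
  stopifnot(is(x, "GroupProbabilities"))
  x@probs
}

#' @rdname phonoGroup
#' @export
probGroup <- function(x, group) {
  stopifnot(is(x, "GroupProbabilities"))
  x@probs[.groupIndex(group)]
}

setMethod("show", "GroupProbabilities", function(object) {
  top <- function(g, n = 3) {
    p <- sort(probGroup(object, g), decreasing = TRUE)[seq_len(n)]
    paste(sprintf("%s %.2f", sub("^.*\\.", "", names(p)), p), collapse = ", ")
  }
  cat("GroupProbabilities\n")
  for (g in c("v1", "c1", "v2", "c2"))
    cat(sprintf("  %s: %s\n", g, top(g)))
  cat(sprintf("  repetition: %.2f; decoded: \"%s\"\n",
              probGroup(object, "r"), renderSSW(decodeArgmax(object))))
})

#' Convolutional model for phonological prediction
#'
#' A convolutional backbone (random-filter feature extractor, frozen during
#' training per the reference regime) followed by three fully connected
#' layers ending in the raw 88-dimensional output. Dropout applies to the
#' first two FC layers during training.
#'
#' @slot config Model configuration list (see [modelConfig()]).
#' @slot conv List of convolution stages (filter tensors + pool sizes).
#' @slot fc List of fully connected layers (\code{W}, \code{b}).
#' @slot inputSize Native square input edge in pixels.
#' @slot featureDim Flattened feature dimension feeding the FC head.
#' @slot featCenter,featScale Per-feature standardization constants fitted
#'   on the training features (identity before training).
#' @export
setClass("SSWModel", representation(
  config = "list", conv = "list", fc = "list",
  inputSize = "integer", featureDim = "integer",
  featCenter = "numeric", featScale = "numeric"
))

setMethod("show", "SSWModel", function(object) {
  cat(sprintf("SSWModel (%s backbone): %d conv stage(s), input %dx%d, %d features -> FC %s\n",
    object@config$backbone, length(object@conv),
    object@inputSize, object@inputSize, object@featureDim,
    paste(vapply(object@fc, function(l) nrow(l$W), 1L), collapse = "-")))
})

#' Fitted model with its learning curve
#'
#' @slot model The trained \linkS4class{SSWModel}.
#' @slot curve Data frame with one row per epoch: \code{epoch},
#'   \code{train_loss}, \code{test_loss}, and (when tracked) \code{acc1},
#'   \code{acc2}.
#' @slot testImages Image ids held out from training.
#' @export
setClass("SSWFit", representation(
  model = "SSWModel", curve = "data.frame", testImages = "character"
))

setMethod("show", "SSWFit", function(object) {
  cv <- object@curve
  cat(sprintf("SSWFit: %d epoch(s); final train loss %.4f%s; %d held-out image(s)\n",
    nrow(cv), cv$train_loss[nrow(cv)],
    if (!all(is.na(cv$test_loss)))
      sprintf(", test loss %.4f", cv$test_loss[nrow(cv)]) else "",
    length(object@testImages)))
})

#' Training pairs of images and phonological targets
#'
#' One row of \code{samples} (and of \code{targets}) per annotated SSW
#' token; images are stored once and referenced by id, so an image annotated
#' with k tokens contributes k pairs.
#'
#' @slot images Named list of H x W x 3 arrays in [0,1].
#' @slot samples Data frame with columns \code{image_id}, \code{ssw}
#'   (canonical romanization).
#' @slot targets Integer matrix, one 88-bit row per sample.
#' @seealso [makePairs()]
#' @export
setClass("SSWTrainingSet", representation(
  images = "list", samples = "data.frame", targets = "matrix"
))

setMethod("show", "SSWTrainingSet", function(object) {
  cat(sprintf("SSWTrainingSet: %d pair(s) over %d image(s), %d SSW type(s)\n",
    nrow(object@samples), length(object@images),
    length(unique(object@samples$ssw))))
})

#' Synthetic texture corpus
#'
#' Procedurally generated texture images with simulated annotations and the
#' ground-truth perceptual parameters that drove both.
#'
#' @slot images Named list of size x size x 3 arrays in [0,1].
#' @slot params Data frame: \code{image_id}, \code{roughness},
#'   \code{glossiness}, \code{softness}, \code{wetness}, \code{granularity},
#'   \code{seed}.
#' @slot annotations Long data frame: \code{image_id}, \code{participant_id},
#'   \code{ssw}.
#' @slot seed Master seed of the corpus.
#' @seealso [genCorpus()]
#' @export
setClass("TextureCorpus", representation(
  images = "list", params = "data.frame", annotations = "data.frame",
  seed = "integer"
))

setMethod("show", "TextureCorpus", function(object) {
  cat(sprintf("TextureCorpus: %d image(s), %d annotation token(s), seed %d\n",
    length(object@images), nrow(object@annotations), object@seed))
})

#' Accessors for corpus and training-set components
#' @param x A \linkS4class{TextureCorpus} or \linkS4class{SSWTrainingSet}.
#' @return The requested component.
#' @export
corpusImages <- function(x) x@images

#' @rdname corpusImages
#' @export
corpusAnnotations <- function(x) x@annotations

#' @rdname corpusImages
#' @export
corpusParams <- function(x) x@params

#' @rdname corpusImages
#' @export
fitModel <- function(x) { stopifnot(is(x, "SSWFit")); x@model }

#' @rdname corpusImages
#' @export
fitCurve <- function(x) { stopifnot(is(x, "SSWFit")); x@curve }

#' @rdname corpusImages
#' @export
fitTestImages <- function(x) { stopifnot(is(x, "SSWFit")); x@testImages }
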