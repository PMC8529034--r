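## Hash results are cached per 72-bit core string; the hash is pure, so the
## cache is a plain lookup table.
.hashCache <- new.env(parent = emptyenv())

#' Correlation-hash bits of a phonological core
#'
#' The 72 non-hash bits (v1, c1, s1, v2, c2, s2, r in layout order) are
#' rendered as a '0'/'1' character string, hashed with MD5, and the first
#' 16 digest bits (most-significant-bit first) become the hash block. The
#' per-slot predictions are otherwise independent; because MD5 mixes the
#' whole code, these bits carry cross-slot correlation information and
#' penalize implausible phoneme combinations.
#'
#' @param core Integer/numeric 0-1 vector of length 72.
#' @return Integer vector of 16 bits.
#' @examples
#' computeHashBits(rep(0, 72))
#' @export
computeHashBits <- function(core) {
  if (length(core) != 72L)
    stop("core must have exactly 72 entries, got ", length(core),
         call. = FALSE)
  core <- as.integer(core)
  if (!all(core %in% c(0L, 1L)))
    stop("core entries must be 0/1", call. = FALSE)
  key <- paste(core, collapse = "")
  hit <- .hashCache[[key]]
  if (!is.null(hit)) return(hit)
  hex <- digest::digest(key, algo = "md5", serialize = FALSE)
  ## first 16 bits of the digest, MSB-first = first two digest bytes
  b2 <- strtoi(c(substr(hex, 1, 2), substr(hex, 3, 4)), base = 16L)
  bits <- as.integer(unlist(lapply(b2, function(x)
    bitwAnd(bitwShiftR(x, 7:0), 1L))))
  assign(key, bits, envir = .hashCache)
  bits
}

.oneHot <- function(symbols, x) {
  v <- integer(length(symbols))
  v[match(x, symbols)] <- 1L
  v
}

.multiHot <- function(symbols, xs) {
  v <- integer(length(symbols))
  v[match(xs, symbols)] <- 1L
  v
}

#' Encode a sound-symbolic word as its 88-bit phonological vector
#'
#' One-hot vowel/consonant blocks and multi-hot special blocks are set from
#' the canonical inventory order; the final 16 bits are
#' [computeHashBits()] of the preceding 72.
#'
#' @param x An \linkS4class{SSWForm}, or a romanized string which is parsed
#'   first.
#' @return A \linkS4class{PhonoVector}.
#' @examples
#' v <- encodeSSW("gowa-gowa")
#' phonoGroup(v, "r")
#' @export
setGeneric("encodeSSW", function(x) standardGeneric("encodeSSW"))

#' @rdname encodeSSW
#' @export
setMethod("encodeSSW", "SSWForm", function(x) {
  core <- c(
    .oneHot(.VOWELS, x@vowel1),
    .oneHot(.CONSONANTS, x@consonant1),
    .multiHot(.SPECIALS1, x@specials1),
    .oneHot(.VOWELS, x@vowel2),
    .oneHot(.CONSONANTS, x@consonant2),
    .multiHot(.SPECIALS2, x@specials2),
    as.integer(x@repetition)
  )
  PhonoVector(c(core, computeHashBits(core)))
})

#' @rdname encodeSSW
#' @export
setMethod("encodeSSW", "character", function(x) encodeSSW(parseSSW(x)))

## Encode many words into an n x 88 integer matrix (rows named by word).
.encodeMatrix <- function(words) {
  m <- t(vapply(words, function(w) phonoBits(encodeSSW(w)), integer(88L)))
  rownames(m) <- words
  m
}

#' Decode probabilities to the most probable form
#'
#' Takes the argmax element of each softmax block; a sigmoid entry
#' (specials, repetition) is included iff its probability exceeds 0.5.
#' Ties resolve to the earlier inventory index. The hash block plays no
#' role in argmax decoding (it only enters candidate scoring).
#'
#' @param probs A \linkS4class{GroupProbabilities}, or a raw 88-dimensional
#'   model output which is passed through [normalizeOutput()] first.
#' @return An \linkS4class{SSWForm}.
#' @examples
#' decodeArgmax(normalizeOutput(as.numeric(phonoBits(encodeSSW("puni")))))
#' @export
setGeneric("decodeArgmax", function(probs) standardGeneric("decodeArgmax"))

#' @rdname decodeArgmax
#' @export
setMethod("decodeArgmax", "GroupProbabilities", function(probs) {
  pick <- function(group, symbols)
    symbols[which.max(probs@probs[.groupIndex(group)])]
  thresholded <- function(group, symbols)
    symbols[probs@probs[.groupIndex(group)] > 0.5]
  SSWForm(
    consonant1 = pick("c1", .CONSONANTS), vowel1 = pick("v1", .VOWELS),
    specials1 = thresholded("s1", .SPECIALS1),
    consonant2 = pick("c2", .CONSONANTS), vowel2 = pick("v2", .VOWELS),
    specials2 = thresholded("s2", .SPECIALS2),
    repetition = unname(probs@probs[.groupIndex("r")] > 0.5)
  )
})

#' @rdname decodeArgmax
#' @export
setMethod("decodeArgmax", "numeric", function(probs) {
  decodeArgmax(normalizeOutput(probs))
})

#' Write phonological vectors as plain text
#'
#' One line per vector: 88 comma-separated 0/1 integers in layout order.
#'
#' @param vectors A \linkS4class{PhonoVector}, a list of them, or an
#'   n x 88 matrix.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
writePhonoVectors <- function(vectors, path) {
  if (is(vectors, "PhonoVector")) vectors <- list(vectors)
  if (is.list(vectors))
    vectors <- do.call(rbind, lapply(vectors, phonoBits))
  stopifnot(is.matrix(vectors), ncol(vectors) == 88L)
  writeLines(apply(vectors, 1, paste, collapse = ","), path)
  invisible(path)
}
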