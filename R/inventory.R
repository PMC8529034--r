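## Canonical phoneme inventories. Every one-hot index in the package derives
## from the listing order here; do not reorder.

.VOWELS <- c("a", "i", "u", "e", "o")

## 26 consonant onsets plus explicit absence ("") as the final entry.
.CONSONANTS <- c(
  "k", "ky", "g", "gy", "s", "sy", "z", "zy", "t", "ty",
  "d", "dy", "n", "ny", "h", "hy", "b", "by", "p", "py",
  "m", "my", "y", "r", "ry", "w", ""
)

.SPECIALS1 <- c("N", "Q", "R")
.SPECIALS2 <- c("N", "Q", "R", "Li")

## Voiced obstruent onsets, used by the association rules and evaluation
## summaries (roughness symbolism).
.VOICED_CONSONANTS <- c("g", "gy", "z", "zy", "d", "dy", "b", "by")
.VOICELESS_CONSONANTS <- c("k", "ky", "s", "sy", "t", "ty", "h", "hy", "p", "py")

## Block layout of the 88-dimensional phonological code, in order.
.LAYOUT <- c(v1 = 5L, c1 = 27L, s1 = 3L, v2 = 5L, c2 = 27L, s2 = 4L,
             r = 1L, h = 16L)
.SOFTMAX_GROUPS <- c("v1", "c1", "v2", "c2")
.SIGMOID_GROUPS <- c("s1", "s2", "r", "h")

#' Phoneme inventories of the phonological code
#'
#' The code describes the first two morae of a sound-symbolic word's
#' repetition unit. Each mora is a consonant (possibly absent) plus a vowel,
#' optionally followed by special phonemes: the moraic nasal \code{N}, the
#' geminate \code{Q}, the long-vowel mark \code{R}, and (second mora only)
#' the word-final liquid suffix \code{Li}.
#'
#' @return Character vector of symbols in canonical (index) order.
#' @examples
#' sswVowels()
#' length(sswConsonants())  # 26 onsets + absence
#' @export
sswVowels <- function() .VOWELS

#' @rdname sswVowels
#' @export
sswConsonants <- function() .CONSONANTS

#' @rdname sswVowels
#' @export
sswSpecials1 <- function() .SPECIALS1

#' @rdname sswVowels
#' @export
sswSpecials2 <- function() .SPECIALS2

#' Layout of the 88-dimensional phonological vector
#'
#' Blocks in order: vowel 1 (5), consonant 1 (27), specials 1 (3),
#' vowel 2 (5), consonant 2 (27), specials 2 (4), repetition (1) and the
#' 16-bit MD5 correlation hash.
#'
#' @return Named integer vector of block lengths summing to 88.
#' @export
phonoLayout <- function() .LAYOUT

## 1-based index range of a named block within the 88-vector.
.groupIndex <- function(group) {
  stopifnot(group %in% names(.LAYOUT))
  off <- cumsum(c(0L, .LAYOUT))[match(group, names(.LAYOUT))]
  seq.int(off + 1L, off + .LAYOUT[[group]])
}

.groupSymbols <- function(group) {
  switch(group,
    v1 = , v2 = .VOWELS,
    c1 = , c2 = .CONSONANTS,
    s1 = .SPECIALS1,
    s2 = .SPECIALS2,
    r = "r",
    h = paste0("h", seq_len(16L)),
    stop("unknown group: ", group)
  )
}

## Names for all 88 positions, e.g. "c1./g/".
.phonoNames <- function() {
  unlist(lapply(names(.LAYOUT), function(g) {
    paste0(g, ".", .groupSymbols(g))
  }), use.names = FALSE)
}
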