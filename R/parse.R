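## Romanized SSW parsing. Input is Hepburn-tolerant; canonical output is
## phonemic (kunrei-style) spelling so that parse and render round-trip.

.HEPBURN <- list(
  "shi" = c("sy", "i"), "sha" = c("sy", "a"), "shu" = c("sy", "u"),
  "sho" = c("sy", "o"),
  "chi" = c("ty", "i"), "cha" = c("ty", "a"), "chu" = c("ty", "u"),
  "cho" = c("ty", "o"),
  "tsu" = c("t", "u"),
  "ji" = c("zy", "i"), "ja" = c("zy", "a"), "ju" = c("zy", "u"),
  "jo" = c("zy", "o"),
  "fu" = c("h", "u"), "fa" = c("h", "a"), "fi" = c("h", "i"),
  "fe" = c("h", "e"), "fo" = c("h", "o")
)

.PALATALS <- c("ky", "gy", "sy", "zy", "ty", "dy", "ny", "hy", "by", "py",
               "my", "ry")
.SINGLE_CONS <- c("k", "g", "s", "z", "t", "d", "n", "h", "b", "p", "m",
                  "y", "r", "w")
.CONS_LETTERS <- c(.SINGLE_CONS, "c", "f", "j")

.unparseable <- function(text, why) {
  stop(sprintf("unparseable SSW \"%s\": %s", text, why), call. = FALSE)
}

## Tokenize one repetition unit into morae:
## list of list(consonant, vowel, specials) in order.
.tokenizeUnit <- function(unit, text = unit) {
  chars <- strsplit(unit, "")[[1]]
  n <- length(chars)
  i <- 1L
  morae <- list()
  canLengthen <- FALSE  # a bare repeated vowel reads as /R/ only right
                        # after the vowel nucleus (or a previous /R/)
  addSpecial <- function(s) {
    if (!length(morae)) .unparseable(text, "special phoneme before any mora")
    m <- morae[[length(morae)]]
    m$specials <- union(m$specials, s)
    morae[[length(morae)]] <<- m
  }
  while (i <= n) {
    rest <- substr(unit, i, n)
    ## apostrophe only separates a moraic nasal from a following mora
    if (substr(rest, 1, 1) == "'") {
      canLengthen <- FALSE; i <- i + 1L; next
    }
    ## Hepburn digraphs/trigraphs
    hit <- FALSE
    for (len in c(3L, 2L)) {
      key <- substr(rest, 1, len)
      if (!is.null(.HEPBURN[[key]])) {
        cv <- .HEPBURN[[key]]
        morae[[length(morae) + 1L]] <-
          list(consonant = cv[1], vowel = cv[2], specials = character())
        i <- i + len; canLengthen <- TRUE; hit <- TRUE
        break
      }
    }
    if (hit) next
    ## palatalized onset + vowel (e.g. "kya")
    c2 <- substr(rest, 1, 2)
    v3 <- substr(rest, 3, 3)
    if (c2 %in% .PALATALS && v3 %in% .VOWELS) {
      morae[[length(morae) + 1L]] <-
        list(consonant = c2, vowel = v3, specials = character())
      i <- i + 3L; canLengthen <- TRUE; next
    }
    c1 <- substr(rest, 1, 1)
    v2 <- substr(rest, 2, 2)
    ## plain onset + vowel
    if (c1 %in% .SINGLE_CONS && v2 %in% .VOWELS) {
      morae[[length(morae) + 1L]] <-
        list(consonant = c1, vowel = v2, specials = character())
      i <- i + 2L; canLengthen <- TRUE; next
    }
    ## bare vowel: lengthening of the previous nucleus or a new onsetless mora
    if (c1 %in% .VOWELS) {
      if (canLengthen && length(morae) &&
          morae[[length(morae)]]$vowel == c1) {
        addSpecial("R"); canLengthen <- TRUE
      } else {
        morae[[length(morae) + 1L]] <-
          list(consonant = "", vowel = c1, specials = character())
        canLengthen <- TRUE
      }
      i <- i + 1L; next
    }
    ## moraic nasal: "n" that does not open a mora ("na", "nya")
    nOpens <- v2 %in% .VOWELS ||
      (v2 == "y" && substr(rest, 3, 3) %in% .VOWELS)
    if (c1 == "n" && !nOpens) {
      addSpecial("N"); canLengthen <- FALSE; i <- i + 1L; next
    }
    ## geminate: doubled consonant letter ("tt", "ss", ...; "nn" is /N/ above)
    if (c1 %in% .CONS_LETTERS && v2 == c1) {
      addSpecial("Q"); canLengthen <- FALSE; i <- i + 1L; next
    }
    ## explicit geminate marker, and word-final "t" as canonical final /Q/
    if (c1 == "q" || (c1 == "t" && i == n)) {
      addSpecial("Q"); canLengthen <- FALSE; i <- i + 1L; next
    }
    .unparseable(text, sprintf("symbol \"%s\" at position %d", c1, i))
  }
  morae
}

#' Parse a romanized sound-symbolic word
#'
#' Splits the word into its repetition unit and the unit into morae, keeping
#' the first two morae with their trailing special phonemes. Repetition is
#' recognized from a hyphen (\code{"gowa-gowa"}) or from exact doubling
#' (\code{"gowagowa"}). Hepburn spellings (\code{shi}, \code{chi},
#' \code{tsu}, \code{ji}, \code{fu}, ...) are normalized to phonemic rows.
#' A word-final \code{"ri"} after two full morae is read as the liquid
#' suffix \code{Li}; longer words are truncated to their first two morae.
#'
#' @param text Non-empty romanized SSW (ASCII letters, optional hyphens).
#' @return An \linkS4class{SSWForm}.
#' @examples
#' parseSSW("gowa-gowa")
#' parseSSW("fuwa-fuwa")  # "fu" normalizes to the /h/ row
#' @export
parseSSW <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text))
    stop("empty SSW input", call. = FALSE)
  s <- tolower(trimws(text))
  if (!grepl("^[a-z'-]+$", s))
    .unparseable(text, "characters outside a-z, apostrophe and hyphen")
  repetition <- FALSE
  if (grepl("-", s)) {
    segs <- strsplit(s, "-", fixed = TRUE)[[1]]
    segs <- segs[nzchar(segs)]
    if (length(segs) < 2L || length(unique(segs)) != 1L)
      .unparseable(text, "hyphenated segments must repeat one unit")
    unit <- segs[1]
    repetition <- TRUE
  } else {
    unit <- s
    half <- nchar(s) %/% 2L
    if (nchar(s) %% 2L == 0L && half >= 3L &&
        substr(s, 1, half) == substr(s, half + 1L, nchar(s))) {
      unit <- substr(s, 1, half)
      repetition <- TRUE
    }
  }
  morae <- .tokenizeUnit(unit, text)
  ## a doubling like "kyakya" can be a single two-mora word (kya+kya), not
  ## a reduplicated one-mora unit: fall back to the whole-word reading
  if (length(morae) < 2L && repetition && unit != s && !grepl("-", s)) {
    unit <- s
    repetition <- FALSE
    morae <- .tokenizeUnit(unit, text)
  }
  if (length(morae) < 2L)
    .unparseable(text, "fewer than two morae in the repetition unit")
  ## word-final "ri" after two morae realizes /Li/
  if (length(morae) == 3L) {
    m3 <- morae[[3]]
    if (m3$consonant == "r" && m3$vowel == "i" && !length(m3$specials)) {
      morae[[2]]$specials <- union(morae[[2]]$specials, "Li")
      morae <- morae[1:2]
    }
  }
  ## words longer than two morae: keep the first two (two-slot code)
  m1 <- morae[[1]]; m2 <- morae[[2]]
  new("SSWForm",
    consonant1 = m1$consonant, vowel1 = m1$vowel,
    specials1 = intersect(.SPECIALS1, m1$specials),
    consonant2 = m2$consonant, vowel2 = m2$vowel,
    specials2 = intersect(.SPECIALS2, m2$specials),
    repetition = repetition, surface = text)
}

.renderMoraBase <- function(consonant, vowel, specials) {
  out <- paste0(consonant, vowel)
  if ("R" %in% specials) out <- paste0(out, vowel)
  out
}

#' Render a form to its canonical romanization
#'
#' Canonical conventions: phonemic consonant rows (so /h/+/u/ is
#' \code{"hu"}), \code{N} as \code{"n"} (followed by an apostrophe when an
#' n-onset reading would be ambiguous, as in \code{"kin'ye"}), \code{R} as
#' vowel doubling, mora-1 \code{Q} as gemination of the following onset
#' (\code{"q"} before a bare vowel), word-final \code{Q} as \code{"t"},
#' \code{Li} as final \code{"ri"}; a hyphen joins the doubled unit iff the
#' repetition flag is set.
#'
#' @param form An \linkS4class{SSWForm}.
#' @return Canonical romanized string.
#' @examples
#' renderSSW(SSWForm("g", "o", character(), "w", "a", character(), TRUE))
#' @export
renderSSW <- function(form) {
  stopifnot(is(form, "SSWForm"))
  u <- .renderMoraBase(form@consonant1, form@vowel1, form@specials1)
  if ("N" %in% form@specials1) {
    u <- paste0(u, "n")
    ## apostrophe keeps /N/ distinct from an n- or ny-onset reading
    if (!nzchar(form@consonant2) ||
        substr(form@consonant2, 1, 1) == "y")
      u <- paste0(u, "'")
  }
  if ("Q" %in% form@specials1) {
    u <- if (nzchar(form@consonant2))
      paste0(u, substr(form@consonant2, 1, 1)) else paste0(u, "q")
  }
  u <- paste0(u, .renderMoraBase(form@consonant2, form@vowel2,
                                 form@specials2))
  if ("Li" %in% form@specials2) u <- paste0(u, "ri")
  if ("N" %in% form@specials2) u <- paste0(u, "n")
  if ("Q" %in% form@specials2) u <- paste0(u, "t")
  if (form@repetition) paste0(u, "-", u) else u
}

#' Canonicalize a romanized SSW token
#'
#' Parse-and-render: maps spelling variants ("fuwafuwa", "fuwa-fuwa",
#' "huwa-huwa") onto one canonical type string.
#'
#' @param text Romanized SSW token(s).
#' @return Character vector of canonical romanizations.
#' @export
canonicalSSW <- function(text) {
  vapply(text, function(t) renderSSW(parseSSW(t)), character(1),
         USE.NAMES = FALSE)
}
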