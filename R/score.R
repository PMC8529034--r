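## Numerically stable primitives.
.logSumExp <- function(z) {
  m <- max(z)
  m + log(sum(exp(z - m)))
}
.rowLogSumExp <- function(Z) {
  m <- apply(Z, 1, max)
  m + log(rowSums(exp(Z - m)))
}
## log sigmoid(z) and log(1 - sigmoid(z)) without overflow
.logSigmoid <- function(z) ifelse(z >= 0, -log1p(exp(-z)), z - log1p(exp(z)))
.softplus <- function(z) ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))

#' Normalize a raw 88-dimensional output to probabilities
#'
#' Softmax within each one-hot block (v1, c1, v2, c2); elementwise sigmoid
#' over the special-phoneme, repetition and hash entries.
#'
#' @param output Numeric vector of 88 raw (pre-normalization) values.
#' @return A \linkS4class{GroupProbabilities}.
#' @export
normalizeOutput <- function(output) {
  stopifnot(is.numeric(output), length(output) == 88L)
  p <- numeric(88L)
  for (g in .SOFTMAX_GROUPS) {
    idx <- .groupIndex(g)
    z <- output[idx] - max(output[idx])
    p[idx] <- exp(z) / sum(exp(z))
  }
  for (g in .SIGMOID_GROUPS) {
    idx <- .groupIndex(g)
    p[idx] <- stats::plogis(output[idx])
  }
  names(p) <- .phonoNames()
  new("GroupProbabilities", probs = p)
}

#' Cross-entropy loss of a candidate word against a model output
#'
#' The composite loss is a sum over the eight blocks: softmax
#' cross-entropy for the one-hot vowel/consonant blocks, elementwise
#' binary (sigmoid) cross-entropy for the special-phoneme, repetition and
#' hash entries — the hash block included, so phoneme combinations whose
#' joint code is implausible score a higher loss even when each slot fits.
#'
#' @param output Numeric vector of 88 raw model outputs.
#' @param form An \linkS4class{SSWForm}, romanized string, or
#'   \linkS4class{PhonoVector} target.
#' @return Non-negative scalar loss.
#' @examples
#' out <- 10 * as.numeric(phonoBits(encodeSSW("gowa-gowa")))
#' scoreCandidate(out, "gowa-gowa") < scoreCandidate(out, "sara-sara")
#' @export
scoreCandidate <- function(output, form) {
  stopifnot(is.numeric(output), length(output) == 88L)
  target <- if (is(form, "PhonoVector")) phonoBits(form)
            else phonoBits(encodeSSW(form))
  loss <- 0
  for (g in .SOFTMAX_GROUPS) {
    idx <- .groupIndex(g)
    z <- output[idx]
    loss <- loss + (.logSumExp(z) - z[target[idx] == 1L])
  }
  for (g in .SIGMOID_GROUPS) {
    idx <- .groupIndex(g)
    z <- output[idx]; t <- target[idx]
    loss <- loss - sum(t * .logSigmoid(z) + (1 - t) * .logSigmoid(-z))
  }
  unname(loss)
}

## Vectorized composite loss: outputs (n x 88 raw) vs targets (m x 88 bits),
## returning the n x m loss matrix. Identity used: per-sample loss =
## sum_g [lse(z_g)] + sum_sig softplus(z) - z . t   (softmax one-hot targets
## contribute -z[hot]; sigmoid blocks contribute softplus(z) - t*z).
.lossMatrix <- function(outputs, targets) {
  if (is.null(dim(outputs))) outputs <- matrix(outputs, nrow = 1)
  stopifnot(ncol(outputs) == 88L, ncol(targets) == 88L)
  sigIdx <- unlist(lapply(.SIGMOID_GROUPS, .groupIndex))
  const <- rowSums(.softplus(outputs[, sigIdx, drop = FALSE]))
  for (g in .SOFTMAX_GROUPS)
    const <- const + .rowLogSumExp(outputs[, .groupIndex(g), drop = FALSE])
  L <- matrix(const, nrow(outputs), nrow(targets)) -
    outputs %*% t(targets)
  dimnames(L) <- list(rownames(outputs), rownames(targets))
  L
}

#' Rank lexicon candidates by cross-entropy loss
#'
#' Scores every lexicon word against the raw output with
#' [scoreCandidate()]'s loss and returns the best \code{k} in ascending
#' loss order. Ties break by descending lexicon frequency, then
#' lexicographically.
#'
#' @param output Numeric vector of 88 raw model outputs.
#' @param lexicon Character vector of romanized words, a named count
#'   vector, or a data frame with columns \code{ssw} and \code{count}.
#' @param k Number of candidates to return (default: all).
#' @return Data frame \code{ssw}, \code{loss}, \code{count}, sorted.
#' @export
rankCandidates <- function(output, lexicon, k = NULL) {
  lex <- .asLexicon(lexicon)
  if (!nrow(lex)) stop("empty lexicon", call. = FALSE)
  enc <- .encodeMatrix(lex$ssw)
  loss <- drop(.lossMatrix(matrix(output, nrow = 1), enc))
  ord <- order(loss, -lex$count, lex$ssw)
  res <- data.frame(ssw = lex$ssw[ord], loss = unname(loss[ord]),
                    count = lex$count[ord], stringsAsFactors = FALSE)
  if (!is.null(k)) res <- utils::head(res, k)
  rownames(res) <- NULL
  res
}

.asLexicon <- function(lexicon) {
  if (is.data.frame(lexicon)) {
    stopifnot(all(c("ssw", "count") %in% names(lexicon)))
    lexicon[c("ssw", "count")]
  } else if (is.character(lexicon) && is.null(names(lexicon))) {
    data.frame(ssw = lexicon, count = rep(1, length(lexicon)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(ssw = names(lexicon), count = as.numeric(lexicon),
               stringsAsFactors = FALSE)
  }
}

#' Enumerate open-vocabulary candidates in probability order
#'
#' Combines per-slot elements of the four one-hot blocks in descending
#' probability order: every combination of within-slot ranks up to
#' \code{depth} is formed and the resulting words are listed by descending
#' product of the chosen slot probabilities. Special phonemes and the
#' repetition flag are fixed at their 0.5-threshold decisions.
#'
#' @param probs A \linkS4class{GroupProbabilities}.
#' @param depth Per-slot rank depth (>= 1); \code{depth = 1} reproduces
#'   [decodeArgmax()].
#' @return Data frame \code{ssw}, \code{probability} (product over the four
#'   slots), in descending probability order.
#' @export
enumerateByRank <- function(probs, depth = 1L) {
  stopifnot(is(probs, "GroupProbabilities"), depth >= 1L)
  slotTop <- function(group, symbols) {
    p <- probs@probs[.groupIndex(group)]
    ord <- order(-p, seq_along(p))[seq_len(min(depth, length(p)))]
    list(symbols = symbols[ord], p = unname(p[ord]))
  }
  tv1 <- slotTop("v1", .VOWELS);      tc1 <- slotTop("c1", .CONSONANTS)
  tv2 <- slotTop("v2", .VOWELS);      tc2 <- slotTop("c2", .CONSONANTS)
  sp1 <- .SPECIALS1[probs@probs[.groupIndex("s1")] > 0.5]
  sp2 <- .SPECIALS2[probs@probs[.groupIndex("s2")] > 0.5]
  rep <- unname(probs@probs[.groupIndex("r")] > 0.5)
  grid <- expand.grid(i1 = seq_along(tv1$p), j1 = seq_along(tc1$p),
                      i2 = seq_along(tv2$p), j2 = seq_along(tc2$p))
  prob <- tv1$p[grid$i1] * tc1$p[grid$j1] * tv2$p[grid$i2] * tc2$p[grid$j2]
  ord <- order(-prob, grid$i1 + grid$j1 + grid$i2 + grid$j2,
               grid$i1, grid$j1, grid$i2, grid$j2)
  words <- vapply(ord, function(k) {
    renderSSW(SSWForm(tc1$symbols[grid$j1[k]], tv1$symbols[grid$i1[k]], sp1,
                      tc2$symbols[grid$j2[k]], tv2$symbols[grid$i2[k]], sp2,
                      repetition = rep))
  }, character(1))
  data.frame(ssw = words, probability = prob[ord],
             stringsAsFactors = FALSE)
}

#' Worked example of normalized model output
#'
#' The per-block probabilities reported for a rough woven-fabric texture:
#' the strongest elements are /o/ 0.56 and /g/ 0.34 in the first mora,
#' /a/ 0.75 and /w/ 0.38 in the second, repetition 0.96, all special
#' phonemes at or below 0.02. Argmax decoding yields "gowa-gowa";
#' rank-depth enumeration surfaces alternatives such as "zara-zara".
#' Probability mass not reported for the listed elements is spread evenly
#' over the remaining inventory entries.
#'
#' @return A \linkS4class{GroupProbabilities}.
#' @examples
#' renderSSW(decodeArgmax(exampleGroupProbabilities()))
#' @export
exampleGroupProbabilities <- function() {
  fill <- function(symbols, named) {
    p <- numeric(length(symbols))
    p[match(names(named), symbols)] <- named
    rest <- which(!(symbols %in% names(named)))
    p[rest] <- (1 - sum(named)) / length(rest)
    p
  }
  groupProbabilities(
    v1 = fill(.VOWELS, c(o = 0.56, a = 0.29, u = 0.08, i = 0.05)),
    c1 = fill(.CONSONANTS, c(g = 0.34, z = 0.22, m = 0.15, b = 0.10)),
    s1 = c(0.02, 0.01, 0.01),
    v2 = fill(.VOWELS, c(a = 0.75, o = 0.11, u = 0.07, i = 0.05)),
    c2 = fill(.CONSONANTS, c(w = 0.38, r = 0.19, s = 0.13, k = 0.09)),
    s2 = c(0.01, 0.02, 0.01, 0.01),
    r = 0.96
  )
}
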