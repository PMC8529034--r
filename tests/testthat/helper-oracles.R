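# Independent oracles and generators used across the suite. The loss oracle
# works directly in probability space (explicit exp/normalize) so it shares
# no code with the package's log-domain implementations.

layoutIdx <- local({
  lay <- phonoLayout()
  off <- cumsum(c(0, lay))
  stats::setNames(lapply(seq_along(lay), function(i)
    seq(off[i] + 1, off[i + 1])), names(lay))
})

oracleLoss <- function(output, bits) {
  loss <- 0
  for (g in c("v1", "c1", "v2", "c2")) {
    z <- output[layoutIdx[[g]]]
    p <- exp(z) / sum(exp(z))
    loss <- loss - log(p[bits[layoutIdx[[g]]] == 1])
  }
  for (g in c("s1", "s2", "r", "h")) {
    p <- 1 / (1 + exp(-output[layoutIdx[[g]]]))
    t <- bits[layoutIdx[[g]]]
    loss <- loss - sum(t * log(p) + (1 - t) * log(1 - p))
  }
  unname(loss)
}

# Moderate-scale raw outputs keep the probability-space oracle exact.
randomOutput <- function() stats::rnorm(88, sd = 3)

obstruents <- c("k", "ky", "g", "gy", "s", "sy", "z", "zy", "t", "ty",
                "d", "dy", "h", "hy", "b", "by", "p", "py")

# Random SSWForm whose canonical rendering is parse-stable: the second mora
# keeps an onset, geminates precede obstruents, and the liquid suffix Li
# only combines with a long vowel.
randomForm <- function() {
  cons <- sswConsonants()
  vows <- sswVowels()
  c2 <- sample(setdiff(cons, ""), 1)
  c1 <- sample(cons, 1)
  s1 <- character()
  if (stats::runif(1) < 0.2) s1 <- c(s1, "N")
  if (stats::runif(1) < 0.2) s1 <- c(s1, "R")
  if (stats::runif(1) < 0.2 && c2 %in% obstruents) s1 <- c(s1, "Q")
  s2 <- character()
  if (stats::runif(1) < 0.15) {
    s2 <- "Li"
    if (stats::runif(1) < 0.3) s2 <- c(s2, "R")
  } else {
    if (stats::runif(1) < 0.2) s2 <- c(s2, "N")
    if (stats::runif(1) < 0.2) s2 <- c(s2, "R")
    if (stats::runif(1) < 0.15) s2 <- c(s2, "Q")
  }
  SSWForm(c1, sample(vows, 1), intersect(sswSpecials1(), s1),
          c2, sample(vows, 1), intersect(sswSpecials2(), s2),
          repetition = stats::runif(1) < 0.6)
}

randomLexicon <- function(n) {
  words <- unique(vapply(seq_len(2 * n), function(i)
    renderSSW(randomForm()), character(1)))
  words[seq_len(min(n, length(words)))]
}

# Worked-example probability table: reported leading entries, remaining
# softmax mass spread evenly over the unlisted inventory elements.
workedProbabilities <- function() {
  fill <- function(symbols, named) {
    p <- numeric(length(symbols))
    p[match(names(named), symbols)] <- named
    rest <- which(!(symbols %in% names(named)))
    p[rest] <- (1 - sum(named)) / length(rest)
    p
  }
  groupProbabilities(
    v1 = fill(sswVowels(), c(o = 0.56, a = 0.29, u = 0.08, i = 0.05)),
    c1 = fill(sswConsonants(), c(g = 0.34, z = 0.22, m = 0.15, b = 0.10)),
    s1 = c(0.02, 0.01, 0.01),
    v2 = fill(sswVowels(), c(a = 0.75, o = 0.11, u = 0.07, i = 0.05)),
    c2 = fill(sswConsonants(), c(w = 0.38, r = 0.19, s = 0.13, k = 0.09)),
    s2 = c(0.01, 0.02, 0.01, 0.01),
    r = 0.96
  )
}
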