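test_that("parsing recovers mora structure and repetition", {
  f <- parseSSW("gowa-gowa")
  expect_equal(f@consonant1, "g"); expect_equal(f@vowel1, "o")
  expect_equal(f@consonant2, "w"); expect_equal(f@vowel2, "a")
  expect_true(f@repetition)
  expect_length(f@specials1, 0); expect_length(f@specials2, 0)

  z <- parseSSW("zara-zara")
  expect_equal(c(z@consonant1, z@vowel1, z@consonant2, z@vowel2),
               c("z", "a", "r", "a"))

  # Hepburn "fu" lands on the /h/ row
  fw <- parseSSW("fuwa-fuwa")
  expect_equal(fw@consonant1, "h"); expect_equal(fw@vowel1, "u")

  p <- parseSSW("puni")
  expect_equal(c(p@consonant1, p@vowel1, p@consonant2, p@vowel2),
               c("p", "u", "n", "i"))
  expect_false(p@repetition)
})

test_that("hyphenation and exact doubling both mark repetition", {
  expect_true(parseSSW("gowagowa")@repetition)
  expect_equal(canonicalSSW("gowagowa"), "gowa-gowa")
  expect_equal(canonicalSSW("fuwa-fuwa"), canonicalSSW("fuwafuwa"))
  # identical morae without reduplication of a one-mora unit
  ry <- parseSSW("ryerye")
  expect_false(ry@repetition)
  expect_equal(ry@consonant1, "ry")
})

test_that("special phonemes attach to the mora they follow", {
  g <- parseSSW("gussuri")   # gu+Q, su, final-ri -> Li
  expect_setequal(g@specials1, "Q")
  expect_true("Li" %in% g@specials2)
  n <- parseSSW("zukin")
  expect_setequal(n@specials2, "N")
  r <- parseSSW("saara-saara")
  expect_setequal(r@specials1, "R")
  # "n" before a geminated "y" onset is the moraic nasal
  b <- parseSSW("binyya")
  expect_setequal(b@specials1, c("N", "Q"))
  expect_equal(b@consonant2, "y")
})

test_that("words longer than two morae are truncated to the first two", {
  k <- parseSSW("karakara-karakara")
  expect_equal(c(k@consonant1, k@consonant2), c("k", "r"))
  expect_true(k@repetition)
  # "ri" followed by more material is a plain mora, not Li
  m <- parseSSW("karari-karari")  # third mora "ri" is last -> Li
  expect_true("Li" %in% m@specials2)
  m2 <- parseSSW("karirin")       # "ri" mora carries N -> ordinary mora 3
  expect_false("Li" %in% m2@specials2)
})

test_that("unparseable input fails with informative errors", {
  expect_error(parseSSW(""), "empty")
  expect_error(parseSSW("xqz!"), "unparseable")
  expect_error(parseSSW("po"), "fewer than two morae")
  expect_error(parseSSW("gowa-zara"), "repeat one unit")
})

test_that("render is canonical and parse-stable on random forms", {
  set.seed(101)
  for (i in 1:300) {
    f <- randomForm()
    s <- renderSSW(f)
    g <- parseSSW(s)
    expect_equal(renderSSW(g), s, info = s)
    expect_equal(g@consonant1, f@consonant1, info = s)
    expect_equal(g@vowel1, f@vowel1, info = s)
    expect_setequal(g@specials1, f@specials1)
    expect_equal(g@consonant2, f@consonant2, info = s)
    expect_equal(g@vowel2, f@vowel2, info = s)
    expect_setequal(g@specials2, f@specials2)
    expect_equal(g@repetition, f@repetition, info = s)
  }
})

test_that("canonicalization collapses spelling variants to one type", {
  expect_equal(canonicalSSW("shittori"), canonicalSSW("syittori"))
  expect_equal(canonicalSSW("tsubutsubu"), canonicalSSW("tubu-tubu"))
  expect_equal(canonicalSSW(c("jara-jara", "zyara-zyara")),
               rep(canonicalSSW("zyarazyara"), 2))
  expect_equal(canonicalSSW("fuka-fuka"), canonicalSSW("huka-huka"))
})
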