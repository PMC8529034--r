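---
title: "From texture images to sound-symbolic words: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From texture images to sound-symbolic words: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TextureSSW)
```

## The problem

Japanese sound-symbolic words (SSWs, onomatopoeia such as *zara-zara*
"rough and dry" or *fuwa-fuwa* "light and fluffy") describe texture at a
finer perceptual resolution than adjectives, and their phonemes carry
systematic sensory associations: voiced obstruents (/g/, /z/, /d/, /b/)
go with roughness, voiceless ones (/s/, /k/, /t/) with smoothness, the
back vowel /u/ with pleasant soft touch, bilabial plosives and /n/ with
soft, sticky, wet feels. TextureSSW models the task of *expressing* a
texture image as an SSW: instead of classifying the image into a fixed
label set, it predicts a probability distribution over the phonological
building blocks of an SSW and then decodes or ranks candidate words.

## The phonological code

An SSW is reduced to the first two morae of its repetition unit. Each
mora is a consonant slot (26 onsets or explicit absence) and a vowel slot
(/a/, /i/, /u/, /e/, /o/), optionally followed by special phonemes: the
moraic nasal /N/, the geminate /Q/, the long-vowel mark /R/ and, after
the second mora only, the liquid suffix /Li/. One bit records whether the
unit reduplicates. The binary code is

| block | v1 | c1 | s1 | v2 | c2 | s2 | r | h |
|-------|----|----|----|----|----|----|---|---|
| width | 5  | 27 | 3  | 5  | 27 | 4  | 1 | 16 |

for 88 bits in total. The v and c blocks are one-hot, s blocks multi-hot.
The final 16 bits, `h`, are a correlation hash: the 72 preceding bits are
serialized as a '0'/'1' character string, digested with MD5, and the
first 16 digest bits (most significant first) are appended. Because each
block is predicted independently downstream, the hash is the only part
of the code that ties slots together: a candidate word whose *joint*
phoneme combination is implausible disagrees with the predicted hash
bits and pays a loss penalty even when every individual slot fits well.
The MD5 serialization (layout-ordered bit string, MSB-first bit
selection) is a fixed convention of this package; any deterministic
choice works, but it must never change once models are trained.

## Romanization conventions

Input is Hepburn-tolerant: *shi, cha, tsu, ji, fu* and friends normalize
onto the phonemic rows (/sy/, /ty/, /t/, /zy/, /h/). Canonical output is
phonemic (kunrei-style) spelling, so `canonicalSSW("fuwa-fuwa")` is
`"huwa-huwa"`. Repetition is recognized from a hyphen or from exact
doubling of a unit of at least three letters; a doubling whose unit would
be a single mora (e.g. *ryerye*) is read as a plain two-mora word.
Word-final /Q/ renders as `t`, /R/ as vowel doubling, /N/ as `n` with an
apostrophe where an n-onset reading would be ambiguous (`kin'ye`), and
/Li/ as a word-final `ri` following two complete morae; a `ri` followed
by more material is an ordinary third mora. Words longer than two morae
keep only their first two (the code has exactly two mora slots). These
conventions make `parseSSW()` and `renderSSW()` mutual inverses on
canonical forms, which the tests verify on hundreds of random words.

## Model and training

The network is a convolutional backbone followed by three fully
connected layers ending in 88 raw outputs. The loss is composite:
log-softmax cross-entropy within each one-hot block (v1, c1, v2, c2)
plus log-sigmoid (binary) cross-entropy over every other entry,
summed — the blocks are independent predictors, and the total
cross-entropy of independent models is the sum of the parts. Batch loss
is the mean over samples of the per-sample sum (the mean/sum choice only
rescales the learning rate). The same quantity, computed for one
image/word pair, is the candidate score used in ranking, and
`compositeLoss()` and `scoreCandidate()` are deliberately two independent
implementations of it that the test suite compares against a third,
probability-space oracle.

Two backbone profiles exist:

* `modelConfig()` — the full-scale profile: a VGG16-style stack
  (13 convolutional + 3 FC layers, 224-px input) with the reference
  training regime as defaults: dropout 0.5 on the first two FC layers,
  SGD with batch size 40, momentum 0.5, learning rate 2.5e-6, 100
  epochs, convolutional layers frozen.
* `smallModelConfig()` — the desk-scale profile used throughout the
  tests: three 3x3 convolution stages (16, 32, 64 channels, 64-px
  input) summarized by per-channel mean and standard deviation of the
  rectified responses ("stats" pooling — translation-invariant texture
  energies in the spirit of classical filter-bank texture features),
  then FC 64-64-88. Its learning rate, 0.01 for 10 epochs, was chosen
  once as a sensible SGD setting for a few hundred images when only the
  FC head trains; the full-scale 2.5e-6 belongs to the 29k-pair regime.

Training honours the frozen-backbone regime: convolutional filters are
seeded random weights that never update, so image features are extracted
once and reused across epochs, and only the FC head receives gradients.
(Unfreezing is rejected with an error rather than silently half
supported.) Feature columns are standardized using means and standard
deviations of the *training* images only; the constants are stored in
the model and applied at prediction time. One training pair is created
per annotated token, so an image described by ten annotators with three
words each contributes thirty pairs; duplicates are kept as duplicates,
which is exactly how the empirical phoneme distribution enters the loss.
Fold assignment is always by image id, so no image spans train and test.

## The synthetic corpus

The real stimulus set (1,946 crops of material photographs with 29,443
collected SSW tokens) is not redistributable, so the package ships a
generative stand-in that the whole pipeline is tested on.

`genTexture()` renders a square texture from five latent perceptual
parameters in [0,1]: a band-limited value-noise base whose cell size is
set by granularity, white noise scaled by roughness, Gaussian blur
proportional to softness, specular-like bright spots in proportion to
glossiness, and a darker, cooler tint with wetness. `simulateAnnotations()`
has each of 10 simulated annotators answer one to six SSW tokens whose
slots are sampled independently from distributions tied to the same
parameters by `defaultAssociationRules()` — the documented associations
(voicing with roughness, /u/ with softness, bilabials and /n/ with
soft-wet, /k/- and /t/-rows with hard-dry) as log-linear coefficients.

Two generator choices deserve explanation. First, slots are sampled
independently; correlations between slots enter only through their
shared dependence on the texture parameters. This is the simplest
generative model consistent with per-phoneme association findings.
Second, the categorical log-weights carry a sharpness factor (default
2.5) calibrated so a simulated corpus is statistically similar to the
reference corpus — a few thousand tokens concentrating on hundreds of
types with a handful of dominant words per image — rather than a
near-uniform draw over the roughly 20,000-word phoneme space, which
would contain no learnable signal and would resemble no human data.

What the generator does *not* emulate: real material appearance
(materials, scenes, lighting), annotator idiosyncrasy and lexical
memory (humans reuse conventional words; our annotators have no
lexicon), and any association the rules do not encode. Passing tests
therefore show that the pipeline recovers planted structure end to end
— not that the model reaches human-level texture description.

## Evaluation

Open-vocabulary decoding takes the per-block argmax (ties resolve to the
earlier inventory index; sigmoid entries activate above 0.5), and
`enumerateByRank()` explores alternatives by descending product of
slot probabilities — the combination rule is a documented package choice,
since "next highest occurrences" does not uniquely order multi-slot
substitutions. Lexicon-restricted evaluation scores every answered word
type by the composite loss and sorts ascending, with ties broken by
descending corpus frequency and then lexicographically. A rank-k
candidate is *correct* if the identical canonical string was among the
words answered for that image — membership, not phonological similarity.
Accuracy is pooled over the held-out images of a fold (per-fold
averaging is available through `crossValidate()`).

The no-signal reference is a label-permutation baseline: the identical
pipeline retrained after whole annotation sets are reassigned randomly
across images. It is a stronger reference than chance because the global
word distribution (and thus a "predict the most common words" strategy)
survives the permutation.

## Scale of the shipped experiments

The packaged acceptance study uses a 200-image corpus (10 annotators,
one to six tokens each, roughly 7,000 pairs), a 40-image holdout (a
larger evaluation fold than 10% keeps the accuracy estimate stable), the
small profile for 10 epochs, and 10 probe textures per condition for the
parameter-recovery check. On one CPU core this completes in about a
minute; the quantities it reports (rank-1/rank-2 accuracy, the
permutation baseline, voiced-consonant mass for rough versus smooth
probes, and the training-loss trajectory) are recomputed from scratch by
`scripts/acceptance.R` at any seed.

## Numerical notes and limitations

* Softmax and log-sigmoid terms are computed in the log domain with
  max-shifted log-sum-exp and branch-stable softplus, so saturated
  outputs score exact zeros/large losses without overflow; ranking
  uses a vectorized identity (per-row constant minus an output-target
  inner product) that is algebraically equal to the per-pair score.
* MD5 hashing is cached per distinct 72-bit core; encoding a 2,000-word
  lexicon touches the digest only once per word.
* All stochastic steps (initialization, dropout, batch order, corpus
  synthesis, annotator sampling, permutation) flow from explicit integer
  seeds and are bit-reproducible; two training runs with one seed give
  identical curves.
* The geminate /Q/ is only sampled before obstruents in test generators
  (its rendering before nasals is not distinctive in romaji), and the
  /Li/ suffix is not combined with /N/ or /Q/; the parser nonetheless
  accepts any such input and canonicalizes it.
* The VGG16-style profile defines the full architecture and regime but
  is not exercised at scale here: with frozen random filters it would
  add cost, not fidelity, and pretrained weights are a runtime option
  deliberately outside the test surface.
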