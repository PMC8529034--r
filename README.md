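# TextureSSW

Expressing the *texture* of a material image — not its category — with
Japanese sound-symbolic words (SSWs, onomatopoeia). Texture description
has no single right answer: the same surface can be *zara-zara* (dry,
rough, unpleasant) to one observer and *gowa-gowa* (stiff, coarse) to
another. Instead of classifying into fixed labels, TextureSSW predicts a
probability distribution over the phonological building blocks of an SSW
and then generates or ranks words from it. The package is for
researchers in visual texture perception, sound symbolism and
cross-modal correspondence who want a complete, reproducible
image-to-word pipeline that runs at desk scale.

## The model

An SSW is encoded as an 88-dimensional binary vector over the first two
morae of its repetition unit:

    v1 (5)  c1 (27)  s1 (3)  v2 (5)  c2 (27)  s2 (4)  r (1)  h (16)

— one-hot vowels and consonants per mora, multi-hot special phonemes
(/N/, /Q/, /R/, and /Li/ in slot 2), a repetition bit, and 16 hash bits
`h` obtained by MD5-digesting the 72 preceding bits. A convolutional
network with three fully connected output layers maps an image to 88 raw
values, trained with the composite loss

    L = Σ_{g ∈ {v1,c1,v2,c2}} CE_softmax(z_g, t_g)
      + Σ_{g ∈ {s1,s2,r,h}}  CE_sigmoid(z_g, t_g)

with SGD (batch 40, momentum 0.5, dropout 0.5 on the first two FC
layers) and a frozen convolutional backbone. The same loss, evaluated
for one image/word pair, scores lexicon candidates: the words with the
smallest cross-entropy loss are the system's first and second candidate
SSWs, and the hash block penalizes phonotactically implausible
combinations that fit well slot by slot. Because per-slot predictions
are independent, `h` is the only carrier of cross-slot correlation.

Since the original annotated photo corpus is not redistributable, the
package includes a procedural texture generator whose latent parameters
(roughness, glossiness, softness, wetness, granularity) drive both the
image and simulated annotators with documented sound-symbolic
associations — so the full train→predict→evaluate loop runs from
nothing and parameter recovery is testable.

## Worked example

Decode the per-block output probabilities of a rough woven fabric:

```r
library(TextureSSW)
probs <- exampleGroupProbabilities()
probs
#> GroupProbabilities
#>   v1: o 0.56, a 0.29, u 0.08
#>   c1: g 0.34, z 0.22, m 0.15
#>   v2: a 0.75, o 0.11, u 0.07
#>   c2: w 0.38, r 0.19, s 0.13
#>   repetition: 0.96; decoded: "gowa-gowa"
head(enumerateByRank(probs, depth = 2), 3)
#>         ssw probability
#> 1 gowa-gowa    0.054264
#> 2 zowa-zowa    0.035112
#> 3 gawa-gawa    0.028101
```

The strongest element of every block combines to *gowa-gowa* ("stiff and
coarse"); the enumeration lists alternative words by descending product
of slot probabilities.

Train on a synthetic corpus and rank candidate words for held-out
images:

```r
corpus <- genCorpus(40, seed = 7)           # 40 textures, 10 annotators each
lex    <- buildLexicon(corpusAnnotations(corpus))
pairs  <- makePairs(corpusImages(corpus), corpusAnnotations(corpus))
ids    <- names(corpusImages(corpus))
held   <- ids[assignFolds(ids, 5, seed = 7) == 1]
fit    <- trainModel(pairs, smallModelConfig(seed = 7), testImages = held)
fit
#> SSWFit: 10 epoch(s); final train loss 17.3436, test loss 18.7398; 8 held-out image(s)

res <- evaluateModel(fit, corpusImages(corpus)[held], lex,
                     answered = answeredSets(corpusAnnotations(corpus)))
head(res, 3)
#>   image_id rank candidate     loss correct
#> 1  img0009    1 pupu-pupu 13.05919   FALSE
#> 2  img0009    2 bubu-bubu 13.06541   FALSE
#> 3  img0009    3 pubu-pubu 14.07617   FALSE
candidateAccuracy(res, answeredSets(corpusAnnotations(corpus)), rank = 1)
#> [1] 0.5
```

Each held-out image gets the lexicon words with the smallest composite
loss; a candidate is `correct` when the same canonical word was among
that image's answered SSWs. Half the rank-1 candidates hit even on this
40-image toy corpus.

A thin command-line wrapper ships in `exec/sswtool`
(`encode`, `decode`, `score`, `synth`, `train`, `predict`, `evaluate`):

```sh
Rscript "$(Rscript -e 'cat(system.file("exec/sswtool", package="TextureSSW"))')" encode gowa-gowa
```

See `vignettes/texture-to-ssw.Rmd` for the phonological conventions, the
model and training regime, the generator's design and its limits.

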