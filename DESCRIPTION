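Package: TextureSSW
Title: Expressing Visual Texture with Japanese Sound-Symbolic Words
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Maps texture images to Japanese sound-symbolic words
    (onomatopoeia) by predicting an 88-dimensional phonological
    probability code with a convolutional network and ranking lexicon
    candidates by composite softmax/sigmoid cross-entropy loss. Includes
    the phonological parser/encoder with an MD5 correlation-hash block,
    mark-based texture cropping, a procedural texture generator with
    sound-symbolically consistent simulated annotators, model training
    with a frozen convolutional backbone, and accuracy evaluation against
    answered-word sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    digest,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
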