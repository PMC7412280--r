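Package: leafvision
Title: Receptor-Noise-Limited Visual Discrimination of Foliage Colours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models how a trichromatic insect eye discriminates host-plant
    foliage of different leaf ages. Converts electroretinogram (ERG) response
    amplitudes into spectral sensitivity curves through the Naka-Rushton
    intensity-response function and decomposes them into three visual-pigment
    nomogram templates (Stavenga 1993; Govardovskii 2000) by bounded nonlinear
    least squares. Normalizes raw reflectance spectra against a white standard,
    integrates normalized reflectance intensity, and evaluates pairwise leaf
    discriminability with the receptor-noise-limited chromatic contrast (delta S,
    in just-noticeable-difference units) and the Michelson achromatic contrast,
    including threshold calls and shoot-zone classification. Ships seeded
    synthetic-data generators for leaf reflectance series, ERG recordings and
    behavioural choice counts so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
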