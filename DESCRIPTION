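Package: cisim
Title: Simulating Cochlear-Implant Speech Processing with Neural Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulation pipeline for studying how cochlear-implant
    channel interaction affects learning in neural networks. Provides a
    synthetic speech generator carrying fine-grained (fundamental frequency,
    formants) and coarse-grained (amplitude envelope) class cues; mel amplitude
    spectrogram featurization at three spectral resolutions, including a
    channel-interaction operator that sums neighboring frequency channels; a
    softmax perceptron and a small convolutional network trained from scratch
    with Adadelta, mini-batches, and early stopping; experiment regimes
    emulating congenitally deaf (training from scratch) and postlingually deaf
    (pre-trained on high-resolution input, then transferred) cochlear-implant
    users; and approximate randomization tests with exact small-sample
    enumeration and Bonferroni correction for paired classifier comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rlang,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
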