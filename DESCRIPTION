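Package: swpkit
Title: Few-Shot Classification of Wound-Induced Plant Slow Wave Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for classifying wound-induced plant slow wave
    potentials (SWPs, also called variation potentials) recorded under
    different light regimes. Provides trace preprocessing (signal
    extraction to the half-recovery point, local mean compression,
    padding, normalization), three feature representations (twelve
    time-domain scalars, first derivative, cumulative integral),
    adversarial-autoencoder data augmentation with VAE and GAN baselines,
    template-similarity quality control (Euclidean distance, Pearson
    correlation, cosine similarity), and multiclass classification
    (SVM, KNN, random forest, MLP) under leave-one-out or k-fold
    protocols with macro-averaged metrics. Includes a synthetic SWP
    generator so the full pipeline can be exercised and tested without
    access to laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
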