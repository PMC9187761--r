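Package: lshgan
Title: Locality-Sensitive-Hashing GAN for Small-Sample Single-Cell Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Generative adversarial model for high-dimension, small-sample (HDSS)
    single-cell expression matrices in which the generator input augments prior
    noise with a locality-sensitive-hashing (LSH) greedy subsample of the real
    cells. Provides the random-hyperplane hash forest and greedy neighbour-
    discarding subsampler, the adversarial training loop (multilayer perceptron
    generator and discriminator trained with ADAM), evaluation by per-feature
    Wasserstein distance and real-versus-generated random-forest AUC, numerical
    verification of the shifted optimal-discriminator theory, and a downstream
    single-cell pipeline (quality-control filters, log normalisation, Fano
    factor, squared coefficient of variation and binned-dispersion gene scores,
    augmentation of real cells with generated cells, and clustering validation
    by adjusted Rand index and normalised mutual information).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    Matrix,
    mclust,
    randomForest,
    pROC,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
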