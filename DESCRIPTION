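Package: odormap
Title: Odor-Impression Prediction from Electron-Ionization Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts 144-descriptor odor-impression profiles of
    monomolecular odorants from their 70 eV electron-ionization mass
    spectra with a nine-layer sigmoid feed-forward network. Two stacked
    autoencoders (greedily pretrained by weight copying) compress the
    spectrum and sensory spaces, a multilayer perceptron maps between the
    two latent spaces, and the assembled network is fine-tuned end to end
    with stochastic gradient descent using a decaying learning rate,
    momentum, an L1 (lasso) penalty and Gaussian noise injection.
    Includes NIST MSP / JCAMP-DX / CSV spectrum readers, m/z windowing
    and max-normalization preprocessing, repeated k-fold cross-validation
    with pooled Pearson-R scoring, PCA and PLS baselines, and a seeded
    synthetic-data generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    mixOmics,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
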