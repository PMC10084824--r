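Package: soilcae
Title: Chaotic Reptile-Search-Tuned Convolutional Autoencoders for Soil
    Fertility Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies soil fertility indices (organic carbon, phosphorus,
    potassium, boron and pH grades) from tabular soil-test reports with a
    one-dimensional convolutional autoencoder whose hyperparameters are tuned
    by a chaotic-enhanced Reptile Search Algorithm. Provides the bounded
    continuous optimizer with logistic-map initialization, opposition-based
    refreshes and a chaotic perturbation schedule; the autoencoder-classifier
    with unsupervised pre-training and supervised fine-tuning; a synthetic
    soil-test-report generator with configurable fertility cut-offs; one-vs-rest
    evaluation tables (accuracy, precision, recall, F-score, MCC); and a
    reproducible end-to-end experiment pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
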