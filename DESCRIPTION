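Package: ethopersist
Title: Persistent Behavioral-State Analysis for Stimulus-Evoked Ethograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying persistent, stimulus-triggered behavioral
    states from frame-classified ethograms of individual animals (groom, walk,
    probe, fly at a fixed frame rate), developed around optogenetic and thermal
    stimulation assays of mosquito host seeking. Provides stimulus-aligned
    population response curves, a nonparametric sliding-window decay half-life,
    a percent-additivity metric for multimodal stimuli, sliding-window
    extraction of a fixed 38-parameter behavioral feature vector, t-SNE
    embedding with density-peak clustering into behavioral states, and a
    resampling-validated (bootstrap and shuffle-null) ridge logistic classifier
    that predicts blood-feeding outcome from pre-stimulus behavior. A
    semi-Markov synthetic ethogram generator with latent arousal states of
    exponential persistence supplies ground-truth cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    mclust,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
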