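Package: eegpain
Title: EEG Feature Extraction and Classification of Tonic Cold Pain States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, feature extraction and machine-learning
    analysis of multichannel EEG for discriminating resting (no-pain) from tonic
    cold-pressor pain epochs. Implements a 380-feature set per 10-second epoch
    (multitaper spectral power and peak frequency, normalized permutation
    entropy, weighted and directed phase lag index connectivity, and weighted and
    binary graph-theory metrics normalized against degree-preserving random
    networks), a movement-artifact feature screen, leave-one-subject-out
    cross-validated classifier sweeps, and permutation-test and bootstrap
    inference on classifier accuracy. A synthetic-EEG cohort generator with
    controllable band power, cross-channel phase-lag structure, condition
    effects and motor-artifact bursts provides ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    e1071,
    rpart,
    glmnet,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
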