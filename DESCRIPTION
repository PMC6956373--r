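Package: eegstress
Title: Hybrid-Feature EEG Stress-State Detection
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects calm versus stress cognitive states from multichannel
    EEG recordings rated on valence/arousal scales. Builds a hybrid pool of
    19 per-channel features (statistical time-domain descriptors, Hjorth
    parameters, and band-specific features from a level-5 db4 wavelet packet
    transform), ranks all relevant features with a shadow-feature wrapper
    around random-forest importance, balances classes with synthetic
    minority over-sampling, and classifies with a k-nearest-neighbour model
    whose k is chosen by stratified cross-validation. Includes a synthetic
    study generator with class-dependent band-power structure, three method
    variants for comparison (feature ranking, PCA compression, all
    features), and one-way ANOVA reporting across datasets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    class,
    optparse,
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
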