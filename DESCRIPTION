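Package: bnmic
Title: Initial-Condition Estimation and Short-Horizon Model Selection for
    Brain Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for synchronizing linear Brain Network Models (BNMs) to
    multivariate BOLD-like timeseries. Implements the Firing Rate Model and
    its null variants on spectrally normalized structural connectomes, a
    recurrent (LSTM) initial-condition estimator trained by one-step-ahead
    prediction through the model propagator, an fMRI-style preprocessing
    chain (bandpass, global signal regression, z-scoring, segmentation),
    and model-selection machinery based on short-horizon trajectory
    accuracy, structural-connectivity sensitivity slopes, and long-term
    functional-connectivity fits. Includes generators for spiral validation
    data and surrogate BOLD from a known model so every analysis is
    reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'connectome.R'
    'dynamics.R'
    'preprocess.R'
    'lstm.R'
    'estimator.R'
    'evaluation.R'
    'io.R'
    'synthetic.R'
    'pipelines.R'
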