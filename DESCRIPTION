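Package: eegcog
Title: Classification of Focused Attention and Working Memory Levels from
    Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for detecting three levels (low, moderate, high) of two
    cognitive skills, focused attention and working memory, from 14-channel
    128 Hz scalp EEG. Provides a synthetic-cohort simulator (1/f background,
    band-limited oscillations with planted class effects, DC offset, spike
    artifacts, skewed cognitive-score distributions), basic preprocessing
    (DC-offset removal, amplitude-outlier rejection, baseline/task
    segmentation), extraction of 210 time-domain features (descriptive
    statistics, Shapiro-Wilk normality, Hjorth mobility and complexity) and
    70 spectral features (Hann-windowed short-time Fourier transform,
    averaged periodograms, relative band powers in theta/alpha/beta/gamma,
    decibel baseline normalization), regularized-logistic-regression feature
    selection, and a stratified k-fold cross-validation harness comparing a
    zoo of standard classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    glmnet,
    randomForest,
    nnet,
    rpart,
    kernlab,
    class,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
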