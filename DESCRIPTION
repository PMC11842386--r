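Package: deepbgs
Title: Hyperspectral Discrimination of Barnyard Grass and Rice Seedlings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies rice and barnyard grass (Echinochloa) seedlings from
    full-range (350-2500 nm) leaf reflectance spectra. Implements the DeepBGS
    pipeline: spectral preprocessing (SNV, moving average, Savitzky-Golay,
    mean centering), a sliding-window transform that turns each 1-D band
    sequence into a 2-D subsequence matrix, and a convolutional network with
    CBAM attention and a bilayer LSTM trained by backpropagation with Adam.
    Also provides feature engineering (vegetation indices, SPA and CARS band
    selection, PCA/t-SNE hooks), classical baseline classifiers, binary
    evaluation metrics (accuracy, MCC, ROC/AUC), and a synthetic leaf
    reflectance generator for end-to-end testing without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    signal,
    stats,
    utils,
    Rcpp,
    e1071,
    rpart,
    randomForest,
    xgboost,
    Rtsne,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
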