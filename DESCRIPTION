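Package: bisguard
Title: Hybrid Local-Model Prediction and Fault Detection for the Bispectral Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the Bispectral Index (BIS) during maintenance-phase general
    anesthesia from the electromyogram (EMG) and the propofol infusion rate, using a
    hybrid intelligent model: K-means partitioning of a lag-embedded 8-input feature
    space with, per cluster, the best of three regression families (multilayer
    perceptron trained by Levenberg-Marquardt, least-squares support vector regression
    with an RBF kernel, and polynomial regression) selected by sample-weighted
    cross-validated mean squared error. A residual-threshold detector compares measured
    BIS against the hybrid prediction to flag sensor readings with null clinical value.
    Includes a propofol PK/PD surgery simulator with EMG burst disturbances and
    injectable sensor faults for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
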