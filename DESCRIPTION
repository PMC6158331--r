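Package: ictalscan
Title: Energy-Efficient Seizure Detection on Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Ictalscan", "Developers", email = "maintainer@ictalscan.dev",
           role = c("aut", "cre"))
Description: A seizure-detection pipeline for intracranial EEG aimed at
    low-power implantable hardware. Provides a synthetic multichannel iEEG
    generator (background activity, low-voltage fast activity and other
    seizure-onset patterns, powerline noise, artifacts), preprocessing
    (local re-referencing, resampling, Butterworth filtering, 1-s epoching,
    artifact rejection), a ten-feature time/frequency feature set including
    line length and a gamma/(alpha+beta) band-power ratio, three per-epoch
    detectors (z-scored line-length thresholding, a Random Forest grown with
    Gini splits and bagging, and an RBF-kernel soft-margin SVM trained by
    grid-searched cross-validation), an evaluation framework (ROC/AUC,
    early-detection AUC, sensitivity, false detections per hour, detection
    delay, leave-one-seizure-out cross-validation), and a simulation of the
    embedded fixed-point deployment (ADC gain and quantization, 16-bit
    feature truncation, 5-byte-per-node forest serialization, short-circuit
    majority voting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
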