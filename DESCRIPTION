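Package: assrfuse
Title: Sleep-State Classification from 40-Hz Auditory Steady-State Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction and classification of 40-Hz auditory steady-state
    response (ASSR) signals for discriminating wakefulness (W0) from deep
    slow-wave sleep (N3). Provides a synthetic stimulus-locked ASSR/EEG
    generator, zero-phase Butterworth band-limiting and sweep segmentation,
    weighted ensemble averaging over sliding sweep windows with
    Kalman-gain-derived weights, a compact learning vector quantization
    (LVQ1) classifier with blind-neuron pruning, feature-level fusion of two
    electrode channels through a single-prototype LVQ, a support vector
    machine baseline, and an evaluation harness reporting error rates,
    false-accept/false-reject rates and equal error rates under same-subject
    and leave-one-subject-out designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
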