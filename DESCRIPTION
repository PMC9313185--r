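Package: erpstates
Title: Brain-State Dynamics in Event-Related Potentials via Gaussian Hidden
    Markov Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Dynamic functional-connectivity analysis of multichannel
    event-related potentials (ERPs). Provides trial averaging and ERP
    component-window amplitude extraction with paired-t electrode selection,
    a maximum-likelihood hidden Markov model with multivariate Gaussian
    emissions whose state covariances are read as functional-connectivity
    patterns (Baum-Welch EM with multi-restart selection, forward-backward
    and Viterbi decoding in C++), state temporal metrics (fractional
    occupancy, mean dwell time, early/late period occupancy), within-subject
    repeated-measures inference for two viewing conditions, and a synthetic
    multi-subject EEG study generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
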