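Package: ssvepid
Title: Person Identification from Steady-State Visual Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biometric person identification from steady-state visual evoked
    potential (SSVEP) recordings. Implements multiclass (one-vs-rest)
    filterbank common-spatial-pattern (FBCSP) feature extraction via the
    generalized eigenvalue decomposition of class covariance pairs, a deep
    feedforward classifier with batch normalization trained by Adam on the
    cross-entropy loss, linear-SVM and k-nearest-neighbour comparators,
    leave-one-block-out cross-validation with the correct recognition rate
    (CRR) and the usability measure U = N*CRR/(Tr + K*Te), and a synthetic
    multi-subject SSVEP generator (subject-specific spatial mixing of
    harmonic sources in broadband noise) so the whole pipeline is testable
    without any dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
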