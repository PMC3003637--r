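Package: qsrrpep
Title: QSRR Retention-Time Prediction and Confidence Grouping for Peptide
    Identifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts reversed-phase gradient liquid-chromatography
    retention times of tryptic peptides from two structural descriptors (a
    retention-factor based hydrophobicity sum and an externally calculated
    logP) via a two-descriptor multiple linear regression, and uses the
    difference between predicted and experimental retention times together
    with charge-dependent Sequest Xcorr thresholds to partition MS/MS
    peptide identifications into four confidence groups: correct,
    incorrect, potential false positive and potential false negative.
    Includes in-silico tryptic digestion, average-mass m/z computation,
    recovery of amino-acid retention factors from printed descriptor
    tables, a synthetic-data generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
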