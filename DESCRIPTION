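Package: nanosubtype
Title: NanoString nCounter Normalization and Nearest-Shrunken-Centroid
    Molecular Subtyping
Version: 1.0.0
Authors@R:
    person("nanosubtype", "developers", email = "nanosubtype@posteo.net",
           role = c("aut", "cre"))
Description: Toolkit for single-sample molecular subtyping of bulk tumour
    RNA profiled on the NanoString nCounter platform. Implements the
    count-to-expression chain used for custom codesets (negative-control
    background thresholding, housekeeping-gene QC, geometric-mean scaling
    to 100, log transform), de novo nearest-shrunken-centroid (PAM)
    classifier training and prediction with centroid-correlation subtype
    scores, Monte Carlo cross-validation, and the paired-classifier
    concordance and enrichment statistics used to certify a classifier.
    Ships a synthetic-cohort simulator emulating a 47-gene basal/luminal
    panel so the full pipeline is testable without any instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
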