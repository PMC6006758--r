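Package: apoloc
Title: Apoptosis-Protein Subcellular Localization from PSSM Profiles
Version: 0.1.0
Authors@R:
    person("apoloc", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the subcellular compartment of apoptosis proteins from
    PSI-BLAST position-specific scoring matrices (PSSMs). Implements two
    profile-based feature extractors - the pseudo-PSSM descriptor (per-column
    means plus lag squared-difference terms) and the detrended
    cross-correlation coefficient over all 190 column pairs - followed by
    supervised dimensionality reduction with local Fisher discriminant
    analysis and one-vs-one RBF support-vector classification evaluated by
    the jackknife (leave-one-out) test. Ships a synthetic PSSM generator so
    the whole pipeline is testable without database searches, plus a
    command-line driver with parameter-sweep modes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
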