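Package: ppiipred
Title: Polyproline II Helix Assignment from Structure and Prediction from Sequence
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Assigns polyproline II helix (PPIIH) residues in protein
    three-dimensional structures by backbone dihedral-angle filtering
    (trans, dihedral and regularity criteria over phi/psi and the
    C-alpha pseudo-dihedral), and predicts per-residue PPIIH propensity
    from sequence with a bidirectional recurrent neural network trained
    by stochastic gradient descent and ensembled over five
    cross-validation models. Includes backbone reconstruction from
    internal coordinates for fixture generation, a proline-window
    baseline, per-residue classification metrics (sensitivity,
    precision, Matthews correlation, ROC/AUC), and synthetic structure
    and sequence corpora so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
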