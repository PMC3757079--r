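Package: idpens
Title: Conformational Ensemble Analysis for Intrinsically Disordered Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize conformational ensembles of intrinsically
    disordered peptides such as the 37-residue islet amyloid polypeptide
    (IAPP, amylin). Provides a seeded generator of synthetic backbone
    conformer ensembles built from helix-coil, helix-hairpin and beta-hairpin
    motifs; hydrogen-bond and dihedral based secondary-structure assignment;
    Kabsch superposition and pairwise C-alpha RMSD; greedy neighbor-count
    (Daura-style) clustering into structural families; rule-based merging of
    families into helix-coil, helix-hairpin and beta-hairpin super-families;
    per-residue RMSF after partial alignment; generalized Born (OBC-style)
    plus surface-area solvation scoring; block-convergence statistics and a
    replica-exchange temperature-ladder utility; and an end-to-end pipeline
    with tabular report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
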