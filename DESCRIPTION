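Package: admscan
Title: Compact-Region Prediction from Average Distance Maps with
    Hydrophobic Packing and Conservation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-only prediction of compact regions (candidate folding
    units) in proteins via Average Distance Maps (ADM): inter-residue
    average-distance statistics binned by sequence separation, density-law
    calibration of per-range cutoff distances, contact-density-difference
    scanning with eta compactness scoring, and comparison against real
    distance maps (RDM) built from coordinates.  Companion analyses locate
    hydrophobic packing pairs in helix bundles by mutual buried
    solvent-accessible surface area, call conserved residues with a
    Poisson lower-tail test on per-column substitution counts from a
    neighbor-joining tree, and extract helix-local hydrophobic spacing
    patterns.  Seeded synthetic-data generators make the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
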