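Package: cleavemap
Title: Extended Protease Cleavage Specificity from Substrate Phage Display
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines extended cleavage specificities of proteases from
    substrate phage display data. Calls the P1 (primary specificity) residue
    set from chromogenic substrate panel kinetics, aligns selected nonamer
    peptides into a fixed P5-P4' subsite frame anchored at candidate P1
    residues, builds positional residue-frequency profiles and
    probability-unit sequence logo matrices with side-chain class groupings,
    and ranks recombinant substrate cleavage efficiencies from first-order
    time courses. A seeded synthetic biopanning simulator (random nonamer
    library, cleavage-driven multinomial selection, clone sampling, kinetic
    time series) provides ground-truth-labelled inputs so every stage of the
    pipeline can be validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    Biostrings
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
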