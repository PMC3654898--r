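Package: hexamyloid
Title: Position-Specific Statistical Potentials for Amyloid Hexapeptide Discrimination
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives position-specific amino acid propensities and statistical
    energy potentials (kcal/mol) from labeled hexapeptide datasets, scores
    peptides with bundled published 20x6 potential matrices for the amyloid-
    fibril and non-amyloid (amorphous beta-aggregate) classes, discriminates
    the two classes with a total-energy-difference sign rule, scans protein
    sequences for aggregation-prone hexapeptide windows, sums per-residue
    property scales such as retention-time hydrophobicity, and evaluates a
    randomized decision-tree ensemble discriminator under stratified k-fold
    cross-validation. Includes a Boltzmann-inversion synthetic peptide
    generator with known class-conditional position-specific biases for
    end-to-end validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    randomForest,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
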