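Package: RNAShapeDesign
Title: Inverse RNA Folding with Shape, Stability and Robustness Constraints
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs RNA sequences whose predicted minimum-free-energy
    structures reproduce the coarse-grained (Shapiro) shape of a target
    secondary structure while matching user-specified thermodynamic
    stability (minimum free energy, kcal/mol) and mutational robustness
    (neutrality in [0,1]). Implements a two-phase search: an adaptive-walk
    initialisation toward the target structure followed by simulated
    annealing with look-ahead sampling over a four-term weighted objective
    (neutrality gap, free-energy gap, Shapiro tree-edit distance, and
    base-pair distance). Includes an ordered tree-edit distance
    (Zhang-Shasha) over weighted Shapiro trees, a hermetic
    dynamic-programming folding backend with stacking energies, an adapter
    for ViennaRNA's RNAfold, a structure fixture generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
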