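Package: kisfold
Title: Coarse-Grained Thermodynamics of RNA Kissing-Loop Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Physics-based, coarse-grained modelling of RNA tertiary motifs
    built around hairpin-hairpin kissing complexes. Computes loop
    conformational entropies by exhaustive self-avoiding virtual-bond walks
    on the diamond lattice, evaluates closed-form pseudoknot and
    freely-jointed-chain loop free energies, builds two-strand partition
    functions, melting profiles and (native, non-native) free-energy
    landscapes for dimer systems at toy scale, and constructs coarse-grained
    A-form virtual-bond 3D scaffolds written as PDB.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
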