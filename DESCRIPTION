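Package: shapealign
Title: Structure-Informed RNA Sequence Alignment from SHAPE Reactivities
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Model-free global alignment of RNA sequences driven by
    nucleotide-resolution SHAPE chemical probing data. Reactivity profiles
    are compared with a clipped linear scoring function and aligned with an
    affine-gap (Gotoh) dynamic program, either from reactivities alone or
    combined with base identity. Includes benchmarking against reference
    alignments (sensitivity), reactivity-difference distribution analysis
    with randomized controls, exhaustive scoring-parameter search, a
    consensus secondary-structure pipeline wrapping the ViennaRNA
    RNAalifold/RNAfold programs with SHAPE pseudo-free energies, and a
    synthetic homolog simulator with known true alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: ViennaRNA (RNAfold, RNAalifold) for the folding pipeline
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
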