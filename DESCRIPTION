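Package: foldinit
Title: Sequence-Based Prediction of Protein Folding-Initiation Segments
Version: 0.1.0
Authors@R: person("Foldinit", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts folding-initiation segments of a protein from its
    amino-acid sequence using inter-residue average distance statistics.
    Builds Average Distance Maps (ADMs), extracts compact regions with eta
    scores, runs a coarse-grained C-alpha Metropolis Monte-Carlo simulation
    under a Gaussian distance potential to produce per-residue F-value
    profiles, computes Shrake-Rupley solvent-accessible surface areas and
    hydrophobic native contacts, profiles evolutionarily conserved
    hydrophobic residues from a multiple sequence alignment, and compares
    predicted segments across a protein family with an ADM-similarity
    metric and neighbor-joining trees. Includes a synthetic-data module
    that generates compact C-alpha chains, two-domain families, and
    alignments with controlled conservation for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
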