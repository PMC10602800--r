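Package: coralign
Title: Correlation-Map-Guided Global Protein Sequence Alignment
Version: 0.1.0
Authors@R: person("Core", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Global pairwise protein alignment that augments a conventional
    20x20 amino-acid substitution matrix with a 400x400 pair-substitution
    matrix applied at correlated residue positions taken from a per-sequence
    correlation (or contact) map. Includes builders for coevolution-derived
    substitution matrices from multiple sequence alignments (mutual
    information and mean-field direct coupling analysis), fixed-size
    embedding signatures via 2D discrete-cosine-transform compression with
    an L1 signature distance used to gate alignment parameters by homolog
    closeness, structural congruence evaluation (Kabsch superposition and
    length-normalized RMSD over matched columns), deterministic synthetic
    data generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
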