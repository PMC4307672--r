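Package: ankrep
Title: Tandem Ankyrin Repeat Detection from Protein Contact Network Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects tandem Ankyrin (ANK) repeats in protein 3-D structures.
    The backbone C-alpha atoms of a chain are turned into a protein contact
    network (binary adjacency at a 7 Angstrom cutoff), the principal
    eigenvector of the adjacency matrix provides a per-residue centrality
    profile, and a rule set over that profile and the secondary-structure
    architecture (anti-parallel helix-turn-helix core, buried first helix,
    peak spacing, core length) locates individual ANK motifs, refines their
    boundaries, and groups them into tandem repeat regions. Includes
    STRIDE/DSSP output parsers, a C-alpha-only geometric secondary-structure
    fallback, Kabsch superposition for motif validation, parametric
    synthetic-fold generators for testing, and batch/report tooling.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
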