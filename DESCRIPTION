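Package: conservscape
Title: Site-Specific Conservation Profiling of Protein Families on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An empirical-Bayes pipeline for per-site evolutionary conservation
    analysis of protein multiple sequence alignments, built around the workflow
    used to profile cytochrome P450 aromatase. Computes posterior mean
    site-specific rates under a discrete-gamma prior via Felsenstein pruning on
    a neighbor-joining guide tree, z-normalizes them into conservation scores
    and nine conservation grades, maps columns to reference (e.g. human
    CYP19A1) residue numbering, summarizes conservation over named regions such
    as substrate recognition sites, classifies residues as family-unique versus
    superfamily-shared from paired alignments, scans clade-stratified alignments
    for degenerate consensus motifs (PKA/PKG phosphorylation sites, the
    heme-ligating cysteine pocket, the EXXR salt bridge), and paints scores into
    PDB B-factor columns for structure coloring. A seeded sequence simulator
    evolving sites at known rates on a birth-process tree provides ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    bio3d,
    yaml,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
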