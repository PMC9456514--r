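Package: pepmap
Title: Subunit Architecture Analysis of the Plastid-Encoded RNA Polymerase
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for characterizing the subunit architecture of
    the chloroplast plastid-encoded RNA polymerase (PEP) and its associated
    proteins (PAPs). Provides sliding-window conservation profiling of core
    subunit alignments with clade subsets, classification of functional-group
    divergence between clades with mapping onto protein structures and
    solvent-accessibility enrichment statistics, processing of crosslinking
    mass spectrometry dipeptide tables into residue-level interaction networks
    and Calpha-Calpha distance assessments, and iBAQ-based label-free
    quantification with stoichiometry estimation. A seeded synthetic-data
    module generates alignments, structures, intensity tables and crosslink
    tables with known ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
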