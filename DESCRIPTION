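Package: ldcsig
Title: Genetic Context, Sequence Signatures and Domain Motions of
    Enterobacterial Lysine Decarboxylases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of the enterobacterial lysine
    decarboxylase family (the acid-stress-inducible LdcI/CadA and its
    biosynthetic paralogue LdcC). Classifies ldc genes as "ldcI-like" or
    "ldcC-like" from their genetic environment (cadB operon partner versus
    accA/yaeR flanks) and audits stated annotations; builds progressive
    multiple alignments with Needleman-Wunsch affine-gap dynamic
    programming; derives per-group consensus profiles and classifies
    sequences from the two C-terminal beta-strand signature regions alone
    (residues 631-640 and 697 to the C-terminus in E. coli LdcI numbering,
    including the diagnostic Y697/K697 dimorphism); designs LdcIC/LdcCI-style
    chimeric sequences by region swap; computes neighbor-joining trees on
    WAG, Poisson-corrected or p-distances with bootstrap supports and
    bipartition tests; and compares decameric structure models domain by
    domain via Kabsch superposition, reporting in-context RMSD against
    optimally superposed RMSD_min to quantify wing-domain anchoring and
    C-terminal-domain swinging and stretching. A seeded synthetic-data
    generator (tree-evolved two-group families with planted signatures,
    matching gene-neighborhood tables, and D5-symmetric toy decamers with
    known rigid-body domain motions) makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    bio3d,
    Rcpp,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
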