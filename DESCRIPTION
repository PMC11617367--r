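Package: dualprot
Title: Dual-Strategy Plasma Proteome Analysis with De Novo Contig Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Integrates library-search peptide identifications with de novo
    peptide contigs for extended-range plasma proteome analysis. Assembles de
    novo reads into contigs with a confidence-weighted de Bruijn graph (k = 8),
    maps contigs to a reference proteome by local alignment with a 75 percent
    identity gate, clusters peptides and contigs at 95 percent identity with a
    greedy centroid scheme, merges per-protein evidence from both strategies
    into coverage, abundance-tier and group-specificity summaries, computes
    peptide physicochemical properties (tryptic status, average mass,
    aliphatic index), and characterizes phosphosites structurally via
    Shrake-Rupley solvent-accessible surface area of intact versus
    phosphorylated models (the K_SASA ratio). A synthetic-cohort generator
    with ground truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
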