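Package: retrotrace
Title: Tracing the Origin, Age and Fate of Retroposed Gene Copies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for reconstructing the evolutionary history of a
    retroposed gene family from a parental mRNA. Screens genomic sequence
    for pseudogene candidates by k-mer seeded local alignment, classifies
    hits as processed or duplicated pseudogenes from polyA traits,
    5'-truncation and intron retention, assesses their coding potential
    (open reading frame integrity, Kozak context, polyadenylation signals),
    builds distance-based phylogenies with bootstrap support and
    majority-rule consensus, dates each retroposition event by Dollo
    parsimony on a dated species tree, scans codon alignments for site-wise
    selection with a counting (SLAC-style) test plus a multi-method
    consensus rule, and verifies protein-level evidence by recomputing
    peptide monoisotopic m/z and sequence coverage from identification
    tables. A retroposition simulator generates synthetic transcripts,
    genomes and lineage evolution along a dated tree with machine-readable
    truth, so every stage is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
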