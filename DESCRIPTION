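Package: mitocompare
Title: Comparative Analysis of Compact Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of small circular mitochondrial
    genomes such as those of panpulmonate gastropods: an annotated-genome data
    model with GenBank and feature-table readers, nucleotide composition and
    strand-skew statistics, intergenic/overlap (gene junction) accounting,
    codon usage and relative synonymous codon usage (RSCU) under the
    invertebrate mitochondrial genetic code, pairwise Ka/Ks estimation by the
    Nei-Gojobori (1986) counting method with Jukes-Cantor correction, circular
    signed gene-order normalization with detection of transpositions and
    reverse transpositions, arrangement-type clustering, and a lightweight
    distance-based (neighbor-joining) phylogeny layer.  A seeded synthetic-data
    generator produces annotated genomes, codon sequences evolved under a
    selectable dN/dS, and scripted gene rearrangements so every stage can be
    exercised without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
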