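Package: mitocomp
Title: Comparative Analysis of Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Mito", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated insect
    mitogenomes: parsing of GenBank flat files and feature tables,
    base-composition and AT/GC-skew statistics, relative synonymous
    codon usage (RSCU), gene-architecture ledgers (overlaps, intergenic
    spacers, strand distribution, circular gene order), pairwise
    molecular-evolution statistics (nucleotide diversity, Nei-Gojobori
    Ka/Ks with Jukes-Cantor correction), construction of concatenated
    partitioned protein-coding-gene supermatrices with a neighbor-joining
    tree, and a seeded synthetic-mitogenome simulator that provides
    ground truth for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
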