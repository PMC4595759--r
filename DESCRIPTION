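Package: codasm
Title: Codon-Barcoded Gene Variant Libraries: Design, Read Simulation and
    De Novo Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deconvoluting pooled full-length gene variant
    libraries from short sequencing reads. Protein sequences are
    reverse-translated into degenerate templates that place IUPAC N/R/Y
    bases at synonymous third codon positions, so that every molecule in
    the library carries a unique combination of codons usable as an
    intrinsic barcode. The package designs such templates and their
    assembly oligonucleotides, simulates pooled libraries (error-prone-PCR
    substitutions, uniform or negative-binomial per-variant copy numbers,
    150 bp paired-end reads with substitution errors), and reassembles
    full-length variants de novo with a codon-frame-modified de Bruijn
    graph: (k-3)-mer nodes joined by k-mer edges, depth-based pruning,
    backbone-flank-anchored seeds, exhaustive seed-to-seed traversal, and
    a coefficient-of-variation read-depth filter that rejects chimeric
    contigs. Assembled contigs are scored against truth sets, classified
    as functional or not, and summarised with codon adaptation index and
    depth-based enrichment ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    seqinr,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
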