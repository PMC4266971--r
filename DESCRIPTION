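Package: chromotag
Title: Query, Bin and Visualize Chromosome-Anchored Genes
Version: 0.1.0
Authors@R:
    person("chromotag", "developers", email = "chromotag@example.org",
           role = c("aut", "cre"))
Description: Offline toolkit for querying chromosome-anchored genes of one or
    more genomes by identifier, functional annotation term, or sequence
    homology (with reciprocal best-hit filtering), visualizing per-bin gene
    densities along chromosomes as heat maps, testing chromosome and
    chromosome-arm enrichment of tagged genes with a one-sided Fisher exact
    test and Bonferroni correction, and filtering candidate genes by
    user-supplied expression matrices, differential-expression lists and
    gene-to-group mappings. Supports physical (bp) and genetic (cM)
    coordinate systems, parses BLAST tabular hit files, ships a lightweight
    built-in nucleotide search for self-contained testing, and includes a
    seeded synthetic-data generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    grDevices,
    jsonlite,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
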