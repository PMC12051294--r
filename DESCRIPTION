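Package: chromoscope
Title: Chromosome-Scaffold Diagnostics from Hi-C Contacts, Ortholog
    Shuffling Entropy, and Polytene Map Expectations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating and interrogating chromosome-scale
    genome scaffolds in the fungus gnat Bradysia coprophila and related
    Diptera. Implements EGGS (Entropy of Gene Group Shuffling), a
    min-max normalized entropy score quantifying inter-chromosomal
    shuffling of single-copy orthologs between species; SCOPE (Scatter
    Clusters Of Paired Ends), a long-range intra-chromosomal Hi-C
    interaction caller based on 2D binned kernel density estimation,
    quantile peak calling, and hierarchical peak clustering, used to
    localize the X-chromosome fold-back regions; expected nucleotide
    distances between chromosomal landmarks derived from polytene map
    zone counts; interval coverage utilities for centromere
    localization from repeat alignments; and synthetic-data generators
    with the statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    withr,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    KernSmooth
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
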