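Package: istrace
Title: Transposase-Centred Detection of Interphylum Horizontal Gene Transfer
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects candidate interphylum horizontal gene transfer (HGT)
    events in bacterial genomes using transposase genes of insertion
    sequences (IS) as the tracer. Implements tetranucleotide composition
    profiling with Kullback-Leibler divergence ranking, non-metric
    multidimensional scaling of tetranucleotide frequencies, inverted-repeat
    (IR) detection in the flanks of transposase genes with a cross-taxon
    end-identity metric, neighbor-joining phylogenies with bootstrap
    support, and an integrated per-element HGT verdict that combines the
    three evidence lines. A Markov-chain synthetic-genome generator with
    ground-truth labels makes every stage testable without downloading
    genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    vegan,
    igraph,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, Phylogenetics, SequenceMatching, HorizontalGeneTransfer
RoxygenNote: 7.3.3
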