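Package: cotrep
Title: Characterization of Tandem Repeat Families from C0t-1 Clone Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of reassociation-kinetics (c0t) clone
    libraries from plant genomes: classification of clones against a labeled
    repeat panel, greedy overlap assembly of novel clones, de novo tandem
    repeat detection with monomer decomposition and consensus building,
    grouping of tandem-bearing clones into minisatellite and satellite
    families with Table-style statistics, array-architecture analysis
    (microsatellite-derived higher-order units, head-to-head junctions,
    conserved palindromic flanks), and genomic abundance estimation from a
    sparse genome sample. A seeded simulator generates synthetic genomes with
    planted repeat families and samples c0t-style clone libraries under
    second-order renaturation kinetics, emitting truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Alignment, Annotation
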