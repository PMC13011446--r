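Package: karyoshift
Title: Chromosomal Rearrangements, Repeat Landscapes, and Divergence Scans
    for Comparative Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying large-scale chromosomal rearrangements in
    comparative genomic data: windowed transposable-element density tracks
    and peak calling against chromosomal percentiles, a permutation test for
    repeat enrichment at inversion breakpoints, collinear synteny-block
    chaining from gene-order anchors with detection of chromosomal fusions,
    translocations and cross-species inversion overlaps, windowed nucleotide
    diversity, absolute divergence and differentiation (pi, DXY, FST) from
    genotype tables that retain invariant sites, and phylogenetic
    generalized least squares regression of karyotype traits under Brownian
    motion. A synthetic-data generator produces repeat landscapes,
    rearranged gene-order anchor tables, two-population genotypes and
    Brownian-motion traits with recorded ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    ape,
    vcfR,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'density.R'
    'enrichment.R'
    'genome-io.R'
    'karyoshift-package.R'
    'phylotrait.R'
    'popgen.R'
    'synteny.R'
    'simdata.R'
    'pipeline.R'
    'utils.R'
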