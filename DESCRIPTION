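Package: crossregnet
Title: Integrated Transcription-Splicing Regulatory Network Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an integrated regulatory network over splicing factors
    (SFs), transcription factors (TFs) and kinases, wiring typed directed
    edges from conserved motif hits: splicing edges when an SF motif falls
    inside the windows flanking an alternative-splicing event of the target
    gene, transcription edges when a TF motif falls in the 5 kb promoter
    upstream of the target's transcription start site. Provides global
    network statistics (clustering coefficient, sparseness) with
    degree-preserving and density-matched null ensembles, per-group inedge
    density distributions with Mann-Whitney comparisons, Spearman
    splicing-vs-transcription correlations, a randomized-group control,
    hypergeometric factor-pair co-regulation scans, tissue-specific
    subnetworks induced by an above-average expression filter, motif
    enrichment against control sequences (Fisher exact test), generic term
    enrichment, and summaries of predicted phosphorylation sites and
    intrinsic protein disorder. A synthetic-data generator with plantable
    effect sizes emulates all required inputs so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'annot.R'
    'crossregnet-package.R'
    'density.R'
    'enrich.R'
    'generate.R'
    'io.R'
    'network.R'
    'pairs.R'
    'pipeline.R'
    'props.R'
    'regions.R'
    'tissue.R'
    'utils.R'
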