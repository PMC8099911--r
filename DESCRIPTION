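Package: anchorTF
Title: Anchored Transcription Factor Co-Occupancy Discovery from
    Regulatory DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts transcription factors that cooperate with an anchor
    TF (for example Klf6) by co-occupancy of growth-relevant regulatory
    DNA. Implements selection of developmentally downregulated gene
    modules from expression time courses (soft-power adjacency,
    topological overlap, tree-cut module detection, fold-change and GO
    gating), activity-by-contact (ABC) pairing of enhancers to genes from
    coverage tracks and Hi-C contacts, anchored motif co-occupancy
    enrichment with position-weight-matrix scanning at a relative-score
    threshold and a binomial Z statistic, core/shell ranking of merged
    TF-target networks, and the axon-growth quantification formulas
    (fiber index, branch frequency). Ships seeded synthetic-fixture
    generators so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
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
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
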