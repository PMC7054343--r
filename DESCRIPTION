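Package: stageCNA
Title: Stage-Specific Recurrent Copy-Number Aberrations and Pathway
    Evolution Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects recurrent somatic copy-number gains and losses
    separately for each tumour pathology stage from discrete per-probe
    aberration calls, using a per-marker permutation test with
    Benjamini-Hochberg false discovery rate control and an iterative
    homogeneous peel-off that expands significant peaks along runs of
    concordantly altered markers. Significant regions are annotated with
    the genes fully contained in them, genes are mapped to pathway gene
    sets with size and cross-stage filters, and a pathway evolution
    network is built by connecting gene-sharing pathways in adjacent
    stages, weighted by the squared-overlap score k^2/(p*q). A seeded
    simulator generates stage-grouped call matrices with planted
    recurrent regions plus matching probe maps, gene annotations and
    pathway databases, so the whole pipeline is testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    fgsea,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
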