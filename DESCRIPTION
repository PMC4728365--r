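Package: triPeaks
Title: Multi-Caller Consensus Analysis of ChIP-Seq Occupancy Peaks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for analysing protein occupancy from
    aligned ChIP-seq tags with weak sequence specificity, such as DNA
    topoisomerase II beta. Three independent simplified peak callers (a
    Poisson local-background window caller, a strand-transition caller and
    a coverage-threshold caller) are combined into merged,
    at-least-two-of-three and stringent three-of-three consensus sets with
    full Venn accounting. Consensus peaks are categorised relative to gene
    models (intragenic, promoter, downstream, 100 kb flanks, gene desert),
    profiled by distance to the nearest transcription start site, and
    intersected with epigenomic feature tracks such as CpG islands and
    histone marks. Position-weight-matrix scanning with exact discretised
    null score distributions supports hypergeometric motif enrichment of
    peak sequences against the whole genome; gene-set enrichment and
    binary-distance Ward clustering complete the statistics layer. A
    seeded simulator generates genomes, gene models, feature tracks,
    strand-asymmetric tag pileups around planted binding sites and planted
    motif instances, together with a machine-readable truth table, so the
    whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
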