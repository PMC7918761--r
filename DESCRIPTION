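Package: met1C
Title: Methionine-Cycle Kinetics and RRBS Differential Methylation of Early Embryos
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how one-carbon (1C) metabolism shapes the
    embryonic methylome. Provides a deterministic kinetic model of the
    methionine cycle (MAT isoforms, GNMT, DNA methyltransferase, AHCY, CBS,
    MTR, BHMT) with enzyme knockouts and forcing protocols to quantify the
    volatility of SAM-mediated transmethylation, and a reduced-representation
    bisulfite sequencing (RRBS) workflow: bismark-style coverage-file import,
    coverage and variant filtering, lambda spike-in conversion QC, per-CpG
    chi-squared (binomial deviance) differential methylation testing with
    Benjamini-Hochberg correction, genomic feature annotation (promoter,
    exon, intron; CpG island, shore), sliding-window clustering of
    differentially methylated CpGs, hypergeometric gene-set enrichment, and
    REML mixed models for imprinted-gene methylation. A seeded synthetic-data
    generator with full ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    pracma,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
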