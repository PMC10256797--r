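Package: ychrtools
Title: Selective-Sequencing Enrichment, Structural-Variant Concordance and
    CpG Methylation Profiling for the Human Y Chromosome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing chromosome-targeted (flow-sorted or
    adaptive-sampling) long-read sequencing experiments. Implements gap- and
    ploidy-aware per-chromosome coverage and enrichment factors, assembly
    contiguity metrics (N50/L50, base-matched downsampling fractions),
    post-caller structural-variant processing (IMPRECISE filtering,
    distance-based indel merging, genotype-quality filtering, size binning,
    repeat-content annotation, phylogeny sharing profiles), cross-platform
    genotype concordance via phi (Matthews) coefficients with Bonferroni
    correction, and a CpG methylation landscape pipeline (coverage filtering,
    quantile normalization, island/shore/shelf/open-sea and gene-feature
    annotation, window tracks, per-island means, dispersion scans, and
    methylome-distance trees). A seeded synthetic-data generator emulates the
    statistical structure of such studies so every stage can be verified
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    limma,
    methods,
    phangorn,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
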