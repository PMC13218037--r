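Package: duochromeQC
Title: Detection and Correction of the Two-Color Chemistry T>G Sequencing
    Artifact
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies and corrects the T>G/A>C substitution artifact
    characteristic of Illumina two-color (NovaSeq-type) sequencing chemistry.
    Provides stringent read trimming and alignment filtering, per-site
    mismatch pileup profiling stratified by alternate allele depth,
    platform-versus-platform two-proportion z-tests with false discovery
    rate control, trinucleotide (COSMIC 96-channel) and flanking-base
    context analysis, and a position weight matrix likelihood-ratio filter
    that flags artifact-prone calls in somatic variant callsets. A
    synthetic paired-platform data generator reproduces the statistical
    structure of matched four-color/two-color experiments so the full
    analysis is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, QualityControl, SomaticMutation, VariantAnnotation
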