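Package: methTF
Title: Prediction of Transcription Factors Driving Aberrant DNA
    Methylation in Cancer
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline to predict transcription factors (TFs) that drive
    aberrant DNA methylation in cancer from methylation-array beta values,
    expression tables, chromatin-accessibility peaks and TF motif models.
    Implements sample quality control by PCA and quadratic discriminant
    analysis, calling of differentially methylated regions (DMRs) by
    Gaussian-kernel smoothing of signed moderated t statistics, genomic
    context classification of DMRs (CpG composition, TSS proximity,
    promoter/intron/intergenic), TF motif enrichment against matched
    control regions with exact hypergeometric tests at an
    information-content-derived scan threshold, integration with TF
    expression to nominate driver TFs, and the overlap and window
    statistics used to validate TF-methylation relationships from binding
    peaks and per-CpG bisulfite calls. A synthetic-data module generates
    genomes, probe manifests, beta matrices with planted DMRs, embedded
    motif instances, expression fold-changes and accessibility peaks so
    the whole pipeline can be exercised and benchmarked without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: DNAMethylation, DifferentialMethylation, MotifAnnotation,
    Epigenetics, Transcription, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
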