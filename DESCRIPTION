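Package: vardiscover
Title: Integrated Discovery and Genotyping of SNVs, Indels, CNVs and
    Repeats from Short-Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrated variant discovery from coordinate-sorted short-read
    alignments against a reference genome. Implements Bayesian genotyping of
    SNVs and small indels from filtered pileups (with local indel
    realignment, duplicate start capping and base-quality capping),
    read-depth copy-number discovery with mean-shift segmentation and
    GC-content correction restricted to uniquely mappable bins, read-pair
    discovery of large deletions and mid-size insertions with Poisson
    significance, detection of repetitive regions from multiply-mapped
    reads, functional annotation and filtering of calls against gene models,
    multi-sample VCF merging, genotype benchmarking (sensitivity, FDR, FPR,
    ROC) against gold-standard call sets, and a pooled-segregant drift
    simulator. A self-contained read simulator generates reference genomes,
    diploid samples with implanted variants, and quality-aware paired-end
    alignments so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    jsonlite,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
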