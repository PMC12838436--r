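Package: lorediag
Title: Long-Read Genome Sequencing Diagnostics Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Interpretive analyses for clinical long-read genome sequencing
    of rare neurological disease: per-read short tandem repeat (STR)
    expansion profiling with interruption-motif detection and promoter
    methylation, imprinted-region methylation z-scores against a control
    pool, read-backed cis/trans phasing of compound-heterozygous variants,
    SMN1/SMN2-style paralog copy-number resolution, derivative-chromosome
    reconstruction from split-read breakpoint junctions with mosaic-fraction
    estimation, and gene-panel filtering with cohort findings aggregation.
    Includes a synthetic aligned-read simulator so every stage can be
    exercised against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, StructuralVariation, VariantDetection, Software
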