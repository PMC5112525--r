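Package: pedtrace
Title: Pedigree Ancestry Reconstruction and Inherited-Allele Tracing from
    Multi-Sample SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs which ancestor contributed each genomic block of a
    bred offspring line from multi-sample SNP genotypes, using sliding-window
    diversity-decreased statistics with bimodal thresholding; traces
    specifically inherited alleles to genes; classifies SNPs by genomic
    feature and coding effect; applies fold-change/p-value filters to
    expression tables and intersects differentially expressed genes with
    inherited-allele genes and promoter transcription-factor binding-site
    networks. Includes a backcross pedigree simulator with known block truth
    so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
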