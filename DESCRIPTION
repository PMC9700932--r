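Package: PFVcattle
Title: Potential Functional Variants and Genomic Prediction for Feed
    Efficiency in Beef Cattle
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detection of potential functional variants (PFVs) for feed
    efficiency from multi-tissue RNA-seq variant calls, and their
    validation by weighted single-step GBLUP genomic prediction.  The
    package derives residual feed intake (RFI) from feedlot records,
    applies GATK-style record quality control and MAF/call-rate filters
    to per-tissue VCFs, tests allele-frequency differences between
    extreme feed-efficiency groups with the Cochran-Armitage allelic
    test, classifies variant consequences against a gene model into
    Ensembl-style impact classes, and evaluates prediction scenarios
    that up-weight chip SNPs adjacent to PFVs in the genomic
    relationship matrix.  A synthetic herd generator (pedigree, gene
    dropping, trait architecture, feedlot records, per-tissue VCFs)
    provides fully reproducible data with the statistical structure the
    pipeline assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
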