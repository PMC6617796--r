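Package: HetScan
Title: Heterozygosity Analysis for Mapping Dominant Trait Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Localizes inherited autosomal-dominant disease variants by
    heterozygosity analysis: a genome-wide moving-average heterozygosity
    scan over VCF genotypes (Stage 1), segmentation of the resulting track
    into regions of increased heterozygosity with local maxima (Stage 2),
    candidate ranking with segment-length filters, empirical genome-wide
    significance by random placement of a null disease variant, and
    carrier/noncarrier discrimination via ROC analysis of top-percent
    scores.  Includes a closed-form linkage-disequilibrium model of
    heterozygosity near an inherited dominant variant and a synthetic
    cohort generator in which carriers share a founder haplotype across an
    unrecombined region, so that every pipeline stage can be exercised
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'HetScan-package.R'
    'discrimination.R'
    'genotype.R'
    'pipeline.R'
    'popgen.R'
    'significance.R'
    'simulate.R'
    'stage1.R'
    'stage2.R'
    'utils.R'
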