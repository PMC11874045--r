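Package: trioppv
Title: Trio Whole-Genome Variant Prioritization for Neurodevelopmental Cohorts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a reusable trio whole-genome sequencing (WGS)
    prioritization pipeline for autism spectrum disorder / intellectual
    developmental disorder (ASD/IDD) cohorts: genotype- and site-level quality
    control of SNVs/INDELs, Bayes-factor de novo scoring over genotype
    likelihoods, Mendelian inheritance classification, rarity filtering,
    compound-heterozygote pairing by parental transmission, dual-caller
    structural-variant consensus with CNV log2-ratio calling, mitochondrial
    heteroplasmy classification, repeat-expansion outlier screening, and
    panel-based prioritization of potentially pathogenic variants with
    per-patient and cohort-level reporting.  A deterministic synthetic-cohort
    generator emits the complete file set (PED, multi-sample VCFs, annotation
    tables, SV call sets, CNV segments, repeat profiles, gene panel, and
    regulatory-element intervals) so the whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
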