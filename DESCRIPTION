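Package: clonepair
Title: Spatial Intra-Tumour Heterogeneity from Paired Tumour Biopsies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of spatial intra-tumour heterogeneity from two
    spatially separated tumour biopsies plus a matched normal sample per
    patient. Provides post-calling variant filters for deep panel
    sequencing (UMI consensus error correction, FFPE deamination artifact
    removal, copy-number-neutrality filtering via imbalanced heterozygous
    germline SNPs, impact-category filtering), shared/private mutation
    classification across the two biopsies, clone assignment from paired
    variant allele frequencies by binomial mixture modelling, pathway
    over-representation analysis with an expressed-gene background, and an
    exact Poisson-binomial test for clonal exclusivity of gene or pathway
    pairs. A synthetic cohort generator with ground-truth labels emulates
    the paired-biopsy study design so that every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
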