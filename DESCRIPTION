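Package: methylotyper
Title: Methylation-Based Patient Subtyping from Salivary Gland Array Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a labial-salivary-gland DNA
    methylation subtyping workflow for Sjogren's syndrome cohorts profiled on
    Illumina 450K/EPIC arrays. Covers probe and sample quality control,
    platform intersection, quantile normalization, empirical-Bayes batch
    adjustment, variational-autoencoder latent embedding, Ward hierarchical
    clustering with severe/mild case subgrouping, cluster-phenotype
    association testing, bump-hunting detection of differentially methylated
    regions with bootstrap family-wise error control, and hypergeometric
    gene-set over-representation analysis. Includes a synthetic-cohort
    generator with planted cluster, batch, and regional methylation structure
    so the full pipeline is testable without access to the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    sva,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
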