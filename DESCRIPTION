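Package: imprintDMR
Title: Imprinted-DMR Methylation Analysis for Neuroblastoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to classify gain and loss of methylation at imprinted
    differentially methylated regions (DMRs) from Illumina 450K-style
    beta-value matrices, summarize alteration frequencies across tumour
    cohorts, integrate allele-specific copy-number profiles to distinguish
    true epimutations from copy-number-driven methylation shifts,
    test associations with clinical and genomic features, and stratify
    overall survival by imprinting status. A deterministic synthetic-cohort
    generator with recorded ground truth supports end-to-end validation of
    every pipeline stage without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
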