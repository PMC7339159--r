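Package: fgfrbridge
Title: Companion-Diagnostic Bridging-Study Analysis for a Multiplex FGFR RT-PCR Panel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for a companion-diagnostic (CDx) bridging
    study of a qualitative multiplex RT-PCR assay detecting FGFR2/3 point
    mutations and fusions in urothelial carcinoma. Implements per-target Ct
    thresholding with run-control QC and sample validity accounting;
    positive/negative/overall percent agreement (PPA/NPA/OPA) between paired
    assays with Wilson score and Clopper-Pearson exact confidence intervals
    and CI-based acceptance rules; objective response rate (ORR) estimation
    with a primary-objective decision rule; a weighted-ORR imputation
    sensitivity analysis with percentile bootstrap intervals; cohort
    representativeness testing (two-group t and chi-square); and a synthetic
    screened-cohort generator so the full pipeline runs and is tested without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
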