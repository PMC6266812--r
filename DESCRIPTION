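Package: prscross
Title: Cross-Trait Polygenic Risk Score Analysis for Small Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of P-value-threshold polygenic risk
    scores (PRS) from GWAS summary statistics in small case-control cohorts.
    Provides readers for summary-statistic tables, dosage VCFs and binary
    phenotype questionnaires; post-imputation variant filters (MAF, INFO) and
    sample call-rate reporting; effect-allele harmonization with strand
    ambiguity handling; additive weighted scoring over a threshold grid with
    combined-cohort standardization; case/reference t-tests, logistic odds
    ratios per standard deviation of PRS, and per-symptom ANOVA against
    prospective follow-up phenotypes. A calibrated synthetic-data generator
    emulates trait-specific GWAS results, case/control dosage cohorts with a
    target standardized PRS shift, and follow-up symptom tables, so the full
    pipeline is testable end-to-end without restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
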