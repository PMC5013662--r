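Package: cescore
Title: Centromere/Kinetochore Expression Score Signatures for Tumour Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives and applies an additive centromere/kinetochore gene
    expression score (CES) for tumour expression cohorts: tumour-versus-normal
    differential-expression screening with a cross-dataset prevalence filter
    and permutation confirmation, panel derivation from prognostic evidence,
    unweighted sum-of-log2 scoring, tertile/quartile/cutpoint stratification,
    association analyses (genomic instability, clinicopathological factors,
    co-expression networks, drug sensitivity with Qn-based robust outlier
    exclusion), Kaplan-Meier/log-rank/Cox survival analysis including
    treatment-stratified hazard tables, and a deterministic synthetic-cohort
    generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
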