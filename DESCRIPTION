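Package: penetrax
Title: Polygenic Modification of Monogenic Kidney Disease Penetrance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying how genome-wide polygenic scores
    modify the penetrance of monogenic kidney disease (ADPKD and COL4A-associated
    nephropathy). Implements qualifying-variant classification under tiered
    evidence models (pLOF, ClinVar-asserted, and predicted-deleterious missense),
    CKD e-phenotyping from serum creatinine and billing codes via the CKD-EPI
    equations, ancestry inference by reference-panel principal-component
    projection with random-forest classification, KING-robust kinship exclusion,
    ancestry- and APOL1-calibrated polygenic scoring, carrier- and
    tertile-stratified logistic association models with fixed-effects
    meta-analysis across cohorts, and a phecode-based phenome-wide association
    scan. Ships a synthetic two-cohort generator with planted monogenic,
    polygenic, ancestry, and APOL1 effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    randomForest,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
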