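Package: aprs
Title: Ancestry-Adjusted Polygenic Risk Scores with Family History Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for assessing the portability of polygenic risk
    scores (PRS) across genetic ancestries. Parses PGS-Catalog-format
    scoring files, harmonizes variants against genotype data (allele
    flipping, strand complements, exclusion of strand-ambiguous SNPs),
    computes standardized weighted scores, projects samples into a
    reference principal-component space for ancestry assignment, and
    derives an ancestry-adjusted PRS (aPRS) by residualizing the score on
    the leading principal components. Downstream analyses include
    percentile risk stratification, joint aPRS-by-family-history groups,
    logistic association models with odds-ratio extraction, discrimination
    evaluation (AUROC and AUPRC on held-out data, with case-control
    downsampling), and Cox proportional-hazards models on the age scale
    with Schoenfeld diagnostics and covariate-adjusted cumulative
    incidence curves. A synthetic two-population cohort generator
    (Balding-Nichols population structure, liability-threshold disease
    model, correlated first-degree family history, proportional-hazards
    onset ages) exercises every stage at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vcfR,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
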