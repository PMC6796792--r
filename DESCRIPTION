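Package: famprs
Title: Polygenic Risk Scores for Obesity in Ascertained Family Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and evaluation of weighted polygenic risk scores
    in ascertained nuclear-family cohorts. Simulates family cohorts with
    Mendelian transmission and phenotype-based ascertainment, applies
    per-SNP quality control (minor allele frequency, call rate, exact
    Hardy-Weinberg test, imputation quality), builds pedigree kinship
    matrices, fits logistic and linear mixed models with a kinship random
    effect by penalized quasi-likelihood and restricted maximum likelihood,
    derives odds-ratio-weighted allele scores, and quantifies their ability
    to stratify obesity (trend and quintile odds ratios, optimism-corrected
    AUC, net reclassification and integrated discrimination improvement,
    variance explained) together with closed-form and Monte-Carlo power of
    a training/target polygenic score design under the liability-threshold
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
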