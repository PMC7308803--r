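Package: prsage
Title: Age-Stratified Polygenic Risk Score Analysis with APOE for Alzheimer's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variant quality control, linkage-disequilibrium pruning, polygenic
    risk scoring with APOE-region exclusion, APOE epsilon-allele diplotype
    calling, pathway-restricted scores, and age-stratified logistic and Poisson
    association models with likelihood-ratio tests, in the design used for
    age-dependent APOE and polygenic-component analyses of Alzheimer's disease.
    Includes a liability-threshold genotype/phenotype simulator with
    linkage-disequilibrium blocks, parental-proxy phenotypes and APOE-linked
    survival, so every stage of the analysis is testable without
    access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
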