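Package: jointGxE
Title: Joint Disease-Endophenotype Models with Gene-Environment
    Interaction for Family Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of genotype and gene-environment interaction
    effects on a disease outcome jointly with a dichotomous
    endophenotype in family samples.  Implements transition
    (endophenotype-conditional), polytomous (baseline-category) and
    disease-only logistic models fitted by generalized estimating
    equations with empirical (sandwich) covariance, working
    independence or relationship-specific working correlation,
    derivation of genotype effects at chosen exposure levels, Wald and
    joint 2-df conditional tests with Bonferroni testing strategies,
    pedigree utilities (relative-pair classification, kinship), a
    family-based simulator of disease, endophenotype, genotype and
    exposure data, and a replicate-level study harness measuring bias,
    power, type-I error and confidence-interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet,
    sandwich
Config/testthat/edition: 3
RoxygenNote: 7.3.3
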