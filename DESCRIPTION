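Package: lvprs
Title: Polygenic Modeling of Left Ventricular Mass with PheWAS and
    Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for studying the polygenic architecture of
    echocardiographically measured left ventricular (LV) mass. Builds an LV
    mass phenotype from echo dimensions via the Devereux formula, applies
    variant- and sample-level genotype quality control, fits a Bayesian
    sparse linear mixed model (BSLMM) by MCMC to obtain per-SNP predictive
    weights, projects the resulting polygenic score into a target cohort,
    scans phecode-based clinical phenotypes for association with the score
    (per-site logistic regression, fixed-effect meta-analysis,
    Benjamini-Hochberg FDR), and evaluates candidate risk factors by
    two-sample Mendelian randomization (inverse-variance weighted, MR-Egger,
    weighted median). Includes a synthetic-cohort generator emulating the
    statistical structure the pipeline assumes, so every stage is testable
    without access to protected health data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
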