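Package: zimbPredict
Title: Predictive Analysis of Zero-Inflated Microbiome Count Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predictive analysis of phenotypes from zero-inflated,
    over-dispersed microbiome OTU count tables with grouped samples. Provides
    per-taxon variable screening with negative binomial, zero-inflated
    negative binomial, and two-part (hurdle) negative binomial mixed models
    fitted by Laplace-approximated maximum likelihood, likelihood ratio tests
    with q-value multiple-testing control, L1-penalized multinomial logistic
    regression on variance-stabilized or presence/absence transformed
    abundances, leakage-safe cross-validation pipelines combining screening
    with penalized or unpenalized classifiers, predictive metrics (error
    rate, relative error reduction, AUC, AUPRC), and a Dirichlet-multinomial
    simulator of grouped, zero-inflated OTU tables with a calibrated logistic
    phenotype model for benchmarking the methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    glmmTMB,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
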