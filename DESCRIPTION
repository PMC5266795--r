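Package: targetmr
Title: Drug-Target Mendelian Randomisation with Weighted Gene-Centric Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for drug-target mendelian
    randomisation studies that combine individual-participant cohort data with
    consortium summary statistics. Provides a calibrated multi-study synthetic
    data generator (Gaussian-copula genotypes with target linkage
    disequilibrium, LDL-mediated outcome effects), per-study additive
    association models with Hardy-Weinberg and additivity quality tests,
    two-level inverse-variance-weighted meta-analysis (fixed and
    DerSimonian-Laird random effects, Cochran Q, I-squared with one-sided
    upper 97.5 percent bound), Wald-ratio scaling of per-allele effects to a
    per-1-mmol/L-lower-LDL basis, weighted gene-centric scores, and the
    accompanying sensitivity analyses (dose-response proportionality,
    leave-one-variant-out, linkage-disequilibrium correction,
    incident/prevalent case stratification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
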