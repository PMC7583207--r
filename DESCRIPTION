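Package: epicohab
Title: Cohabitation-Dependent Familial Models for Epigenetic Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree-based analysis of variation in DNA-methylation
    (epigenetic) age across the lifespan. Computes epigenetic age
    acceleration residuals, estimates familial correlations for twin,
    sibling, parent-offspring and spouse pairs under a multivariate normal
    family model, fits cohabitation-dependent correlation and
    variance-components models (AE, cohabitation AE/ACE/CE and CE plus a
    constant additive genetic component) by maximum likelihood, and
    compares models via AIC and likelihood-ratio tests. Includes a
    synthetic family-cohort generator emulating a pooled multi-study
    twin/family design so every stage is testable without access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
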