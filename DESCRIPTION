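Package: famburden
Title: Rare-Variant Collapsing Tests for Quantitative Traits in Family Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Burden (collapsing) association tests for the collective effect of
    multiple rare variants on quantitative traits measured in families. Rare
    variants of a gene are collapsed into a single carrier indicator (Li-Leal
    presence/absence coding) and tested under a unified linear mixed model
    Y = Xb + Qv + Zu + e with six adjustment schemes: plain regression (REG),
    principal-component covariates (PC), a pedigree kinship random effect
    (KIN), a marker identity-by-state random effect (IBS), and their
    combinations (PC-KIN, PC-IBS). Includes pedigree kinship computation,
    genotype utilities (MAF, IBS matrix, Eigenstrat-style PCA), a spectral
    REML fitter for the variance components, a gene-dropping family-study
    simulator, and an evaluation bench producing Q-Q, false-positive-rate and
    truncated-ROC summaries for method comparison.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
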