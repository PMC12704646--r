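Package: trialmr
Title: Forecasting Off-Target Drug Effects with Trial Proteomics and
    Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A genetic-proteomic framework for forecasting off-target drug
    effects from randomized-trial proteomics and genome-wide association
    study (GWAS) summary statistics. Selects cis protein quantitative trait
    locus (pQTL) instruments with a two-study winner's-curse split, LD
    clumping, instrument-strength and cross-protein pleiotropy filters;
    estimates protein-to-outcome causal effects with from-scratch
    implementations of the Wald ratio, fixed-effects inverse-variance
    weighted, weighted median, weighted mode and MR-PRESSO estimators;
    orients estimates to trial-observed protein changes and classifies
    concordance with trial outcomes; and runs reverse Mendelian
    randomization to separate upstream mediators from downstream
    consequences. Ships a summary-level simulation module with known ground
    truth so every pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
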