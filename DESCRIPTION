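Package: remnantmr
Title: Remnant Cholesterol, LDL and ASCVD Risk via Mendelian Randomisation
    and SNP Effect-Ratio Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the relative atherogenicity of triglyceride-rich
    lipoprotein (TRL) remnant particles and low-density lipoprotein (LDL)
    particles from lipid-panel and genotype data.  Provides derivation of
    non-HDL cholesterol, TRL/remnant cholesterol and Sampson-equation VLDL
    cholesterol from standard lipid panels; GWAS-style per-variant association
    scans with tiered significance selection, greedy linkage-disequilibrium
    pruning, allele-frequency and heterozygote-count filters and a
    Bonferroni-Holm lipoprotein(a) exclusion filter; summary-statistics
    Mendelian randomisation estimators (multivariable inverse-variance
    weighted, MR-Egger, contamination mixture) with per-unit and
    per-population-SD odds-ratio reporting; classification of variants into
    receptor-pathway-like and lipolysis-pathway-like clusters from the ratio
    of apolipoprotein-B to TRL/remnant-cholesterol effect sizes; polygenic
    apoB-raising-allele scores with decile Cox proportional-hazards models,
    hazard-ratio scaling per 10 mg/dL apoB and cluster interaction tests;
    observational Cox models and restricted-cubic-spline exposure-ratio
    models.  Includes a synthetic cohort generator emulating the genetic
    architecture, lipid covariance and censored event process the analyses
    assume, so the full pipeline is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
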