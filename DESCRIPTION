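Package: pathprs
Title: Gene-Set Polygenic Risk Scores and Quantitative-Trait Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds pathway (gene-set) polygenic risk scores from GWAS
    summary statistics and individual genotypes: maps a gene list to
    flanked autosomal windows, selects and harmonizes variants, applies
    P-value thresholds, and computes log-odds-ratio-weighted scores.
    Tests score-phenotype association by covariate-adjusted linear
    regression with incremental variance explained, combines per-platform
    estimates by fixed-effect inverse-variance meta-analysis with
    Cochran's Q and I-squared heterogeneity, and provides post hoc power
    for the partial F test via the noncentral F distribution. Includes a
    synthetic cohort generator (Hardy-Weinberg genotypes, planted
    log-odds effects, Gaussian phenotypes with a configurable incremental
    r-squared) so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
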