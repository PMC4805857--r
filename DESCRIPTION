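Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with per-SNP
    summary statistics: allele harmonisation across studies,
    inverse-variance-weighted (IVW), multivariable, and Egger-regression
    causal estimators, Cochran Q heterogeneity, empirical inference by
    resampling of summary statistics, leave-k-SNPs-out sensitivity scans,
    fixed-effects meta-analysis with observational-scale conversion,
    design-based and retrospective power calculations, and a synthetic
    summary-statistics generator with known causal ground truth for
    method validation. Results are tidy tibbles with broom-style tidy()
    and glance() methods and ggplot2 forest/funnel helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
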