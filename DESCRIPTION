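Package: mrpath
Title: Two-Sample Mendelian Randomization Screening and Two-Step Mediation
    for GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: reading and harmonizing summary-statistic tables,
    selecting genetic instruments (genome-wide significance, LD clumping,
    outcome-association exclusion, F-statistic and MAF strength filters,
    LD-proxy substitution), five causal-effect estimators (inverse-variance
    weighted, MR-Egger, weighted median, weighted and simple mode), a full
    sensitivity suite (Cochran's Q, Egger intercept, MR-PRESSO global /
    outlier / distortion tests, leave-one-out), strict multi-gate screening
    of exposures, and two-step product-of-coefficients mediation analysis
    with reverse-MR exclusion. Includes a synthetic GWAS summary-statistic
    generator with known ground truth for validating the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
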