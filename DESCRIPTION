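Package: rbcscreen
Title: Building Maternal Red Blood Cell Antibody Screening Databases from
    Birth Registers and Free-Text Laboratory Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing population-based maternal red blood cell
    (RBC) alloantibody databases by linking birth-register records to
    free-text antibody screening results from regional blood-center
    laboratories. Provides record linkage within a configurable pregnancy
    time window, pattern-based extraction of specific antibody mentions
    (with an anti-D prophylaxis exclusion rule), county-by-year coverage
    assessment with a sustained-coverage inclusion rule, stratified
    prevalence tabulation per 10,000 births, and chart-review style
    validation with exact binomial confidence intervals. A synthetic
    registry generator with known ground truth makes every pipeline stage
    testable without access to confidential registers.
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
    jsonlite,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
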