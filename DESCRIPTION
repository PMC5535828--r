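Package: dilirisk
Title: Dose, Lipophilicity and Metabolism Risk Factors for Drug-Induced
    Liver Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Rule-based hepatotoxicity risk-factor analysis for tabular
    drug datasets in the style of DILIrank. Provides binary risk
    predicates over daily dose, lipophilicity (logP) and extent of
    hepatic metabolism, including the Rule-of-Two (daily dose >= 100 mg
    and logP >= 3); majority-vote consensus annotation across several
    independent DILI label sources with positive tie-breaking;
    2x2 association statistics (sample odds ratio, Wald confidence
    interval, single-covariate logistic fit, and a two-sided Fisher
    exact test computed by hypergeometric enumeration); cross-dataset
    concordance summaries for rule-positive and rule-negative drugs;
    and a synthetic cohort generator with known ground truth for
    calibration and parameter-recovery experiments.
License: MIT
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
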