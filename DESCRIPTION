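Package: metabostrat
Title: Multinomial Biomarker Stratification by Threshold Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for stratifying serum and plasma metabolomics cohorts with
    simple threshold classifiers. Implements a formate-only binomial classifier
    and a (glucose, formate) multinomial decision tree whose thresholds are
    selected by maximising the relative mutual information between imputed and
    reference class labels, together with prevalence-corrected true and false
    positive rates, repeated Monte-Carlo cross-validation with percentile
    summaries, permutation tests, volcano-plot differential statistics, a
    seeded synthetic-cohort generator, and internal-standard peak-area
    quantification of formate.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
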