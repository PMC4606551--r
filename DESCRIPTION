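Package: darules
Title: Dynamic Association Rules for Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistically principled association rule mining for discretized
    gene expression data. Minimum-support and minimum-confidence thresholds are
    derived per rule from the null distributions of support and confidence under
    independence of antecedent and consequent: support via a one-sided normal
    upper bound on a binomial proportion, confidence via the exact discrete null
    distribution of the ratio of two binomial counts. Includes the discretization
    schemes used in two-colour microarray, single-channel microarray and RNA-seq
    case studies (lowess MA normalization, median/IQR scaling, fixed thresholds,
    fold-change labelling, per-gene z-score labelling), a rule miner with
    single- and double-gene antecedents, screening of ambiguous (conflicting)
    rules, synthetic data generators for calibration, tabular IO and a command
    line interface.
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
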