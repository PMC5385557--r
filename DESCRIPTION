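Package: cbpnarm
Title: Context-Based Positive and Negative Association Rule Mining for
    Microbial Energy Prospection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines positive and negative association rules from tabular
    microbial prospection databases (soil microbial indicator observations
    collected per site and time interval, with a Boolean hydrocarbon
    prospect outcome). Implements classical Apriori frequent-itemset
    mining, the support-confidence-interestingness framework for positive
    and negative rules, context-variable support adjustment for records
    collected under abnormal environmental conditions (temperature,
    salinity, humidity, rainfall or fossil pollution outside their normal
    [CIV, CFV] range), and temporal consolidation of per-interval rule
    sets. Includes a synthetic database generator with planted rules and
    injected context anomalies so the whole pipeline is testable without
    field data.
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
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
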