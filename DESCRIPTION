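Package: comorbidr
Title: Rule-Based Detection of Comorbid Conditions in Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid rule-based/machine-learning pipeline that detects 18
    medical conditions (the 16 Charlson-index comorbidities plus tobacco and
    alcohol consumption) in French clinical notes. Regex-dictionary named
    entity recognition is followed by qualification (negation, hypothesis,
    family-history and generic false-positive detection, either rule-based or
    via a trainable snippet classifier), stay-level aggregation, Charlson
    comorbidity index computation, and an ICD-10 claim-code comparator.
    Includes an entity- and stay-level evaluation framework with bootstrap
    confidence intervals and a deterministic synthetic-corpus generator so
    the full pipeline can be exercised and validated without access to
    protected clinical data.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
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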