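Package: oncotimelines
Title: Patient-Level Anticancer Therapy Timelines from Clinical Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for extracting patient-level systemic anticancer
    therapy (SACT) timelines from free-text clinical notes. Implements
    drug-mention tagging (dictionary and trainable BIO sequence labeler),
    grammar-based detection and normalization of time expressions anchored
    on the document creation time, pairwise event-time temporal relation
    classification (rule-based, trainable, or plug-in), deduplicating
    timeline summarization, a two-step few-shot prompting pipeline against
    a pluggable text-generation backend, multi-granularity patient-level
    macro-F1 evaluation, and a synthetic oncology-note generator that
    emits corpora with aligned gold annotations and timelines for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lubridate,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
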