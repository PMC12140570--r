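Package: relbandit
Title: Relative Value Encoding in Bandit Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for studying relative (context-dependent) versus absolute
    outcome encoding in multi-armed bandit experiments with a learning phase
    and a transfer test. Ships five benchmark task structures, builds
    exact-frequency outcome schedules, simulates choice sessions from a family
    of eight Rescorla-Wagner variants (range-normalized outcome encoding,
    confirmation-bias learning rates, softmax response with position bias),
    fits the family by pooled maximum likelihood with BIC comparison, model
    recovery and leave-one-run-out cross-validation, computes relative-value
    bias statistics against an ideal reward-maximizing agent, renders and
    parses the natural-language prompts used to run language models through
    the tasks, and probes hidden-layer activation matrices with per-unit
    linear regressions on absolute- and relative-value differences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
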