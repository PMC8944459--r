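Package: fuzzystay
Title: Fuzzy-Logic Discretization and k-Modes Profiling of ICU Therapy and
    Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-parameter fuzzy domains (three overlapping triangular
    subsets flanked by two trapezoidal shoulders) automatically from population
    statistics, converts daily antimicrobial-therapy records and hourly bedside
    monitoring records into linguistic category patterns, clusters the unique
    patterns with a k-modes algorithm selected by the elbow method, and joins
    the cluster labels into per-stay synoptic tables, contingency tables and
    charts. Includes a seeded synthetic-cohort generator so every stage is
    testable without hospital data.
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
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
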