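Package: addictomir
Title: Food-Addiction Phenotyping, miRNA Differential Expression and
    YFAS 2.0 Scoring from Operant Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native analysis pipeline for rodent food-addiction
    studies and their human translation. Simulates operant-conditioning
    sessions (fixed-ratio, progressive-ratio, shock-test, cue-probe and
    reversal schedules) for a cohort of agents with latent vulnerable and
    resilient phenotypes; scores the three addiction-like criteria
    (persistence of response, motivation via the progressive-ratio breaking
    point, compulsion-like behavior) and four phenotypic traits from event
    logs; classifies animals with the 75th-percentile 2-of-3 rule; builds a
    gradual severity scale and selects extreme discovery and replica
    subgroups; runs a negative-binomial Wald test with median-of-ratios
    normalization and Benjamini-Hochberg correction on miRNA and mRNA count
    matrices; tests discovery/replica replication and miRNA-target
    enrichment with hypergeometric statistics; and scores the 35-item
    YFAS 2.0 instrument with hallmark composites and sex-stratified
    miRNA correlations.
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
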