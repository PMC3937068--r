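Package: fusescreen
Title: Rank-Based Screening of Exon Array Data for Fusion-Gene Breakpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate fusion genes from summarized exon-array
    expression matrices by scanning each transcript cluster for an intragenic
    5'/3' expression discontinuity. Probe sets are filtered on annotation
    quality (evidence level, cross-hybridization class) and signal intensity,
    samples are ranked per probe set, and every admissible cut point splitting
    the cluster into 5' and 3' terminal groups is scored by the difference in
    mean ranks with a standard-deviation guard against measurement noise.
    Includes post-screening triage rules (transcript-isoform explanation,
    multi-gene clusters, reference-sample similarity), a synthetic exon-array
    simulator with injected breakpoints for power and false-positive
    evaluation, exon-expression profile plots, and a command-line interface.
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
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
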