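Package: accordnet
Title: Accordance-Based Longitudinal Functional Connectome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for longitudinal resting-state functional
    connectivity analysis at the network level: motion scrubbing of BOLD
    network time courses via framewise displacement and DVARS with
    neighbor-volume censoring and a retention-based inclusion rule;
    estimation of subject-level connectomes with the accordance
    coactivation/codeactivation statistic on threshold-gated standardized
    signals; definition of a maturating circuitry of interest by edge-wise
    paired t-tests with Benjamini-Hochberg false-discovery-rate control;
    and a between-group intervention-effect test based on sqrt(2)-scaled
    differences of normal-quantile-transformed p-values. Includes a
    synthetic two-group, two-session cohort generator with planted
    coupling structure and motion artifacts, so every stage can be
    validated against ground truth.
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
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
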