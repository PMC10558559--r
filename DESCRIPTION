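Package: neuroload
Title: Cognitive Workload and Performance Evaluation from EEG Functional
    Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for evaluating cognitive workload and task
    performance from multichannel EEG. Raw recordings are decontaminated
    (common-average re-referencing, notch and band-pass filtering, an
    amplitude/variance artifact screen, and a spherical-spline surface
    Laplacian), turned into per-band coherence networks on one-second
    windows, and summarised as dynamic functional-network features --
    temporal flexibility from consensus Louvain community partitions,
    module-allegiance integration and recruitment, search information,
    and node strength -- alongside Kaiser-window Welch band-power
    features, aggregated over Brodmann areas or cortices. A statistical
    layer relates per-trial features to performance and workload scores
    via linear random-intercept models with subject-blocked
    cross-validated forward selection, and via L1-penalised mixed models
    with BIC lambda selection and local-outlier-factor screening. A
    synthetic-data module generates coupled band-limited EEG sources and
    outcome tables with subject random effects so every stage is testable
    without real recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    lme4,
    purrr,
    rlang,
    signal,
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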