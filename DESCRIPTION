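Package: netstress
Title: Network-Restricted Connectivity Strength Analysis for Pre/Post-Stressor
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Fisher z-transformed functional connectomes from parcellated
    resting-state fMRI timeseries and computes network-restricted strength (NRS),
    the mean within-network connectivity over all node pairs of an intrinsic
    connectivity network such as the default mode network. Provides the full
    statistical battery for a two-group (PTSD vs MDD), two-scan (pre vs post
    stressor) repeated-measures design: 2x2 mixed-model GLM via its exact
    algebraic reduction to t contrasts, simple effects and percent differences,
    covariate-adjusted interaction tests, nodal exploration with false discovery
    rate control, split-half scan-duration analysis, delta-strength/severity
    correlations, and a noncentral-t power module for minimum detectable effect
    sizes. Includes a seeded synthetic-cohort generator with block-covariance
    BOLD timeseries and injectable group, stress, and within-run drift effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
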