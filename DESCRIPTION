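Package: gaitsig
Title: Velocity-Dependent Gait Signature Analysis for Rodent and Human Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives stride-to-stride spatiotemporal gait parameters (stride
    length, swing/stance duration, cadence, swing speed) from footfall events,
    fits linear, one-phase and two-phase exponential models of each parameter
    against stride velocity over a restricted walking range, and decides by
    extra sum-of-squares F-tests whether two datasets share one
    parameter-versus-velocity curve or require separate curves, i.e. whether an
    intervention shifted the gait signature beyond what its velocity change
    predicts. Includes the conventional speed-independent contrast analyses
    (normality-gated t/rank tests, multi-group routing, paired-t power), a
    synthetic stride-data generator with parkinsonism-like signature-shift
    presets, CSV/JSON input-output and ggplot2 visualisation.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
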