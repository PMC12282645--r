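Package: scratchval
Title: Analytical Validation of Nocturnal Scratch Digital Health Technologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analytically validating digital health technologies
    (DHTs) that detect nocturnal scratching against a human-annotated video
    reference. Implements half-open interval algebra for scratch events
    (gap merging, minimum-duration filtering, intersection-over-union),
    multi-round rater consensus with an IoU threshold, total sleep
    opportunity (TSO) derivation and short-TSO exclusion, epoch-level
    classification scoring with micro-averaged confusion matrices,
    night-level normalized scratch outcomes, repeated-measures
    Bland-Altman analysis, and intraclass correlation from nested
    mixed-model variance components with cluster-bootstrap confidence
    intervals. A calibrated synthetic-study generator provides ground
    truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
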