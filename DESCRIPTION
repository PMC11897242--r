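Package: reachdev
Title: Developmental Visuomotor Adaptation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how feedforward adaptation and online feedback
    control develop through childhood in gradual visuomotor-rotation reaching
    games. Provides the trial schedule and error-clamp logic of the Push ball
    and Launch ball paradigms, a state-space simulator of age-parameterised
    synthetic participants, per-trial reach-trajectory kinematics (initial,
    final, launch and compensation angles, path-length ratio, correction
    timing, angle spread), epoch summaries with inverse/logarithmic/exponential
    developmental curve fits, and LMS (Box-Cox Cole-Green) age-conditional
    percentile reference curves with quantile-residual diagnostics. Sessions
    round-trip through a JSON-lines format and a single seeded pipeline runs
    simulation through centile estimation reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
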