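Package: reachlearn
Title: Reach Segmentation, Outcome Scoring and Learning Statistics for
    Rodent Skilled Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the single-pellet skilled-reaching task in
    mice, working from markerless pose-estimation output. Reads pose tables in
    the DeepLabCut CSV dialect, filters tracked points by likelihood and spatial
    bounds, segments individual reaches with a directional-vector consensus
    algorithm, computes per-reach kinematics (path length, vertical spread,
    horizontal extension), scores behavioural outcomes (success, complete miss,
    contact miss, vain, no-try), and runs longitudinal learning statistics
    (repeated-measures ANOVA or mixed-effects models, Day-1 versus Day-8 paired
    tests with a Shapiro-Wilk normality gate, Welch tests on per-animal Learning
    Indices). Includes a synthetic-session generator that emulates the task's
    trial structure with controllable learning effects, so every stage is
    testable without video data.
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
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
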