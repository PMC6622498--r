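Package: lexigaze
Title: Individualized Lexico-Semantic Structure and Toddler Word Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for relating the structure of a toddler's productive
    vocabulary to real-time word recognition measured with eye tracking.
    Builds per-child lexico-semantic networks from feature norms and
    computes word-level degree, category-level semantic density, and the
    lexicon-level global clustering coefficient; preprocesses
    looking-while-listening gaze streams (area-of-interest labelling,
    50 ms binning, comprehension and track-loss filters) into a
    trial-level log-gaze proportion ratio; and fits linear mixed-effects
    models with sum-coded predictors and item random intercepts.  A
    synthetic-cohort generator with known effect structure supports
    end-to-end testing and parameter-recovery studies without access to
    any child data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    ggplot2,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    lmerTest,
    optparse
Config/testthat/edition: 3
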