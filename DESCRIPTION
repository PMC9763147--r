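Package: fluxcap
Title: Extracellular Flux Analysis of Sperm Energy Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracellular flux analysis (EFA) of sperm
    bioenergetics. Reads well-level oxygen consumption (OCR) and
    extracellular acidification (ECAR) kinetic traces from plate assays,
    background-corrects and normalizes them to per-sperm rates, derives
    the mito-stress and glycolysis-stress bioenergetic parameter panel
    (basal respiration, proton leak, ATP-linked respiration, maximal and
    spare respiratory capacity, basal glycolysis, glycolytic reserve,
    OCR/ECAR ratio) and percent-of-baseline modulator responses,
    quantifies ATP content from luminescence standard curves, and
    compares capacitating and non-capacitating incubation conditions with
    random-intercept mixed models (Gaussian on log10 scale or gamma with
    inverse link), likelihood-ratio tests and marginal-means contrasts.
    Includes a hierarchical synthetic plate generator with recorded
    ground truth for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    lme4,
    emmeans,
    generics,
    jsonlite,
    digest,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
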