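Package: zebrapref
Title: Closed-Loop Social-Preference Experiments with Virtual Stimulus Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seedable desk-scale simulator and analysis pipeline for closed-loop
    place-preference experiments in zebrafish. Virtual stimulus-fish motion
    controllers (chasing, fleeing, flipped, motionless, playback) are driven in
    real time by the tracked position of an experimental fish; an agent-based
    fish model stands in for live subjects; a synthetic overhead color+depth
    camera and a detector-gated tracker close the loop at the image level.
    The package builds the full within-subject session schedules with side
    counterbalancing, scores time-in-compartment preference as pooled log10
    time ratios, and runs the complete inferential chain: AICc-based
    random-effects structure selection, linear mixed-effects models,
    likelihood-ratio tests, estimated marginal means, and Holm-Bonferroni
    adjusted post hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    lmerTest,
    emmeans,
    EBImage,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr
Config/testthat/edition: 3
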