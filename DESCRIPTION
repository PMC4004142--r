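Package: eatlog
Title: Adherence Analysis of Photographic Dietary Self-Monitoring Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A retrospective cohort pipeline for usage event logs from a mobile
    dietary self-monitoring app with crowdsourced peer feedback. Reads flat
    tables of users, food pictures, peer ratings, likes and comments; applies
    the exclusion rules (empty-picture removal and a peer-rating-count validity
    check on each user's first two pictures); classifies users into adherence
    levels, dietary-preference categories and registration-time bins; runs the
    inferential battery (Pearson chi-square homogeneity tests, a Bonferroni
    corrected weekday-by-daypart grid scan, one-way ANOVA from raw data or
    printed summaries, Tukey HSD for means and for arcsine-transformed
    proportions, pooled two-sample t); and detects per-user linear trends in
    crowdsourced healthiness ratings. A synthetic cohort generator with
    adherence archetypes makes every stage testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
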