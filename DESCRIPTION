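Package: lianepi
Title: Co-Occurrence of Vascular Epiphytes and Lianas on Host Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for co-occurrence of vascular epiphytes and
    woody climbers (lianas) on host trees in forest census plots.
    Reads and validates tree/liana/epiphyte census tables, summarises
    occurrence at tree-zone, tree and forest-patch scales (continuity-
    corrected chi-square association tests, shared-host percentages),
    contrasts host counts with negative-binomial log-link models, fits
    Bayesian hurdle-Poisson, hurdle-lognormal and cumulative-ordinal
    mixed models of richness, basal area and cover against forest type
    and stem diameter, builds weighted bipartite interaction matrices,
    and tests spatial association of host trees with a ring-differenced
    Ripley K statistic against covariate-adjusted random-labelling
    envelopes. Includes a synthetic forest-stand generator emulating the
    sampling design so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    MASS,
    coda,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmmTMB,
    spatstat.geom,
    spatstat.explore,
    optparse
Config/testthat/edition: 3
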