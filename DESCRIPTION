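Package: ctidebt
Title: Community Temperature Index Trends, Climatic Debt, and
    Protected-Area Effectiveness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify how ecological communities track climate
    warming, contrasting sites inside and outside protected areas. Computes
    species temperature indices (STI) from range masks and temperature
    climatologies, per-survey community temperature indices (CTI) and their
    standard deviation (CTI_SD), fits Gaussian and Poisson mixed models with
    site random intercepts and exponential spatial correlation (via glmmTMB),
    converts temporal trends to latitudinal displacement velocities and
    climatic debt, classifies colonization/extirpation scenarios, runs
    moving-window grid-cell regressions of community change on protected-area
    coverage, and provides a species-resampling robustness analysis together
    with a mechanistic occupancy simulator for synthetic waterbird-like
    communities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    lme4,
    mgcv,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
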