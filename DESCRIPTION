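Package: lueled
Title: Light- and Energy-Use Efficiency of Supplemental LED Lighting in
    Greenhouse Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying the efficiency of supplemental
    LED lighting in greenhouse crop experiments with a within-treatment light
    gradient. Provides photometric accounting (band integrals of lamp spectra,
    red:far-red ratios, PPFD/DLI/energy conversions), Beer-Lambert canopy
    light absorption with thermal-time (growing degree day) leaf-area
    interpolation, light-use and energy-use efficiency estimation, per-curve
    dose-response fitting (log-linear versus monomolecular, compared by
    F-test), and a two-stage linear mixed-model analysis of slope and
    intercept efficiencies across light colors, seasons and harvests, with
    estimated marginal means and compact letter displays. A synthetic
    experiment generator reproduces the statistical structure of a
    three-color, four-season, replicated gradient design so every stage is
    testable end to end without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
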