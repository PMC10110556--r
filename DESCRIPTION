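Package: gsmeta
Title: Meta-Analysis of Stomatal Conductance Responses to Global Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A random-effects meta-analysis pipeline for leaf stomatal
    conductance (g_s) responses to global change factors (elevated CO2,
    warming, precipitation change, nitrogen deposition, elevated ozone).
    Computes log response-ratio effect sizes and standardized sensitivities,
    pools them with the "shifting the unit of analysis" weight adjustment for
    non-independent observations, tests subgroup heterogeneity across biomes
    and plant functional types, fits linear and restricted-cubic-spline
    meta-regressions on treatment and climate moderators, classifies
    two-factor interactions against the additive expectation, screens for
    publication bias with funnel plots and Egger's regression, and projects
    end-of-century g_s change per biome from pooled sensitivities and
    scenario forcings. Includes a synthetic-data generator with known ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    readr,
    testthat (>= 3.0.0),
    knitr,
    jsonlite
Config/testthat/edition: 3
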