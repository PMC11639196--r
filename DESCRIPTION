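Package: phenosense
Title: Spatially Explicit Phenological Temperature Sensitivity from
    Community-Science Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for estimating intraspecific variation in
    phenological temperature sensitivity across species ranges. Derives
    per-observation climate covariates (seasonal standardized temperature
    and precipitation, long-term mean annual minimum temperature and its
    interannual variability) from gridded monthly climate series, fits
    interaction linear models of phenology day-of-year, and extracts
    estimated marginal slopes of standardized temperature across a grid of
    historic climate conditions, with delta-method standard errors and
    Tukey HSD adjusted pairwise contrasts. Includes a synthetic-data
    generator with a known parametric sensitivity surface so every stage
    of the pipeline can be verified by parameter recovery.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
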