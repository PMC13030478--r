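Package: invrisk
Title: Integrated Invasion-Risk Mapping from Suitability, Habitat
    Degradation and Spatial Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for national-scale invasive-plant risk
    assessment on gridded landscapes. Screens occurrence records (spatial
    thinning, minimum-record filter, target-group background), fits
    presence-background maximum-entropy species distribution models with
    L1 regularization, stacks per-species binary maps into a potential
    species-richness surface zoned by Jenks natural breaks, models habitat
    degradation with distance-decayed threat kernels and a half-saturation
    quality index, attributes spatial heterogeneity of richness with the
    geographical-detector q-statistic, and intersects high-suitability and
    high-vulnerability habitat into core invasion habitat for protected-area
    gap analysis. Includes a synthetic-landscape generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
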