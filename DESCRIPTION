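Package: partnerscape
Title: Climate-Change Adaptation Benefits of Protected-Area Partnerships
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the climate-change adaptation benefits that protected
    areas (PAs) could gain by partnering with neighbouring protected and
    non-protected land. Five biodiversity adaptation indicators -- land and
    freshwater area, latitudinal range, elevational range, relief-weighted
    hydrologic area, and climate-area velocity -- are computed over discrete
    circular moving windows at multiple partnership scales, evaluated under
    two partnership scenarios and two null models (isolated pixels; isolated
    administrative PAs), then max-normalized and combined into a [0,1]
    adaptation-potential surface with zonal (biome/ecoregion) summaries.
    Includes a synthetic-landscape generator (Gaussian-hill terrain, D8-derived
    drainage networks, blob-grown PA mosaics, elevation- and
    latitude-correlated climate with smooth future deltas) so the full
    pipeline is testable without external rasters, plus a plain-text grid
    format for fixtures and a pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
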