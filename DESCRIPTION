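Package: ricb
Title: Rapid Initial Community Builder for LANDIS-II
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts a gridded plot-imputation raster (TreeMap-style, one
    forest-inventory plot id per forested pixel) and a tree-level inventory
    database into the initial-communities inputs the LANDIS-II forest
    landscape model requires: a mapcode raster, a species-age-biomass cohort
    lookup table, and a species parameterization list. Per-tree aboveground
    biomass is computed with the Jenkins allometric equations and tree age by
    inverting Carmean site-index height curves. Includes raster clipping to an
    area of interest, sequential mapcode remapping, mode aggregation to
    coarser resolution, and a synthetic-landscape generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
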