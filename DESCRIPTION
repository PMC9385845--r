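Package: palumbus
Title: Annual-Cycle Segmentation, Kernel Home Ranges and Ring-Recovery
    Mapping for Partially Migratory Woodpigeons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the movement ecology of facultative partial migrants,
    built around satellite (Argos) and GPS tracking of Common Woodpigeons
    (Columba palumbus) and European ring-recovery data. Provides location
    quality filters (Argos location classes, a 30 m/s speed sweep),
    segmentation of tracks into breeding, migration, stopover and wintering
    phases with midpoint-rule migration phenology, Epanechnikov kernel
    utilization distributions with href bandwidths and 50 and 95 percent
    volume contours, land-cover composition of home ranges, circular
    statistics of foraging flight directions (Rayleigh test), ANOVA-based
    repeatability of site use, and line-density mapping of mark-recovery
    data. A fully ground-truthed individual-based simulator of
    partial-migrant annual cycles, categorical land-cover rasters and
    ring-recovery sets makes every stage testable without access to raw
    tracking archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
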