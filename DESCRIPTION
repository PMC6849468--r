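Package: nuephen
Title: Image-Based Vegetative Screening of Wheat for Nitrogen Use
    Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for automated, image-based vegetative screening of
    wheat germplasm for nitrogen use efficiency (NUE). Segments green
    plant material from RGB side- and top-view images taken in a
    conveyor phenotyping platform (with a blue support cage removed by
    colour classification), derives pixel-sum digital traits (estimated
    shoot biomass and top-view area in kilopixels), fits a continuous
    two-segment "broken-stick" regression to biomass growth series to
    locate the linear growth phase, derives the common linear-phase
    window across varieties and a recommended screening day, and
    computes NUE ratios, harvest index, two-way ANOVA summaries
    (s.e.d., l.s.d., CV) and Pearson trait-correlation reports. A
    synthetic-data module generates images with known pixel labels,
    growth series with known breakpoints and variety-by-nitrogen trait
    tables with known correlation structure so the whole pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    png,
    yaml,
    jsonlite,
    MASS,
    igraph,
    EBImage,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff
Config/testthat/edition: 3
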