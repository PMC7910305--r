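Package: rivershift
Title: Riverbank Habitat Dynamics, Regime Shifts, and Crocodylian Nesting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking riverbank vegetation change to crocodylian
    nesting decline. Computes the Enhanced Vegetation Index (EVI) from
    Landsat-style surface reflectances, classifies riparian habitat plots
    from ground cover fractions and from EVI (five-class and merged
    three-class threshold schemes), calibrates and validates threshold
    schemes with confusion matrices and Cohen's kappa, detects changepoints
    in the mean and/or variance of per-site EVI time series (PELT, binary
    segmentation, and exhaustive dynamic programming) and applies a
    "no return" criterion to declare habitat regime shifts, fits and
    selects linear, exponential, and logarithmic nest-count versus EVI
    relations with subsample-averaged p-values, and summarises nest-site
    usage tables. A seeded synthetic riverscape generator emulates seasonal
    water/sand oscillation, woody encroachment after a disturbance, and
    declining nest counts, so the whole pipeline is testable without a
    satellite archive.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
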