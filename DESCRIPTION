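Package: iplstrat
Title: Morphometry of Inner Plexiform Layer Stratification in Retinal OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies the pentalaminar reflectivity pattern of the retinal
    inner plexiform layer (IPL) in ultrahigh-resolution optical coherence
    tomography (OCT) B-scans. Provides a synthetic retinal-phantom generator
    with fully developed speckle, axial frame registration and intensity
    averaging, layer-boundary segmentation by second-derivative zero
    crossings, extraction of normalized reflectivity profiles on a
    percent-IPL-thickness axis, polynomial-fit stratification into five
    strata yielding 14 morphometric parameters with template-guided
    segmental search and discard rules, topographic aggregation by
    eccentricity and IPL thickness, and subject-level fixed- and
    mixed-effects models including a quadratic eccentricity model with
    vertex estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
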