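Package: canopymix
Title: Rapeseed Yield Estimation at Flowering via Spectral Mixture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating oilseed rape (rapeseed) yield from
    flowering-stage multispectral imagery. Implements fully constrained
    least-squares (FCLS) spectral unmixing of canopy pixels into flower,
    leaf and soil abundances, empirical-line radiometric calibration of
    digital-number images using reflectance panels, a common
    vegetation-index suite (NDVI, CIgreen, VARI, RVI, DVI, RDVI, EVI, TVI,
    NDYI), plot-level aggregation, linear yield models of vegetation
    indices and their abundance products evaluated by leave-one-out
    cross-validation, and confusion-matrix accuracy assessment. A
    synthetic-scene generator emulating a nitrogen-gradient field trial
    makes the whole pipeline testable without field or satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
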