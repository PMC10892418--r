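Package: metalrisk
Title: Pollution Indices and Ecological Risk Assessment for Heavy Metals in Soil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing heavy-metal pollution of agricultural topsoil
    from georeferenced sample tables: the geo-accumulation index (Muller index),
    the Nemerow composite pollution index, and the Hakanson single-factor (Er)
    and composite (PERI) potential ecological risk indices, each with its
    standard grading scheme; district-level descriptive statistics and
    variation coefficients; Pearson correlation with significance annotation
    and standardized principal component analysis with Kaiser retention for
    source apportionment; inverse-distance-weighted interpolation onto regular
    grids with ESRI ASCII export; and a seeded Gaussian-copula lognormal
    generator of synthetic sample sets so the whole pipeline can be exercised
    and tested without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    yaml,
    Matrix,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
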