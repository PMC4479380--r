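Package: weatherSDM
Title: Temporally Explicit Weather-Based Species Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds species distribution models from presence-only records and
    monthly gridded weather. Derives eight bioclimatic covariates over trailing
    12- and 36-month windows (and 30-year climatologies), fits an L1-penalised
    maximum-entropy presence-background model with a bias-matched target-group
    background, projects habitat suitability month by month over decades,
    binarises suitability at the equal training sensitivity/specificity
    threshold to obtain a core-habitat area series, and relates that series to
    a spotlight-count abundance index through at-most-one-change changepoint
    detection and segmented regression. Includes a synthetic island generator
    (weather, occurrences with shared sampling bias, transect counts) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
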