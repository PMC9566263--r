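Package: aerequity
Title: Dynamic PM2.5 Exposure, Walkability and Equity Analysis on Gridded Cities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for dynamic fine-particulate (PM2.5) exposure-equity
    analysis at block and community scale. Fits hourly geographically weighted
    regressions of station PM2.5 on aerosol optical depth, population density,
    NDVI, road density and distance to industry, predicts onto a fishnet grid,
    interpolates by ordinary kriging and averages to blocks; computes
    mobility-aware exposure intensity and time-activity-weighted concentrations
    for age groups from origin-destination commuting flows; scores walkability
    with facility weights, distance decay and street-form attenuation; classifies
    risk typologies with hourly tertile scoring and Jenks natural breaks; and
    quantifies equity with Lorenz/Gini curves and bivariate local Moran (LISA)
    permutation inference. Ships a synthetic monocentric city generator so the
    full analysis runs and is validated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
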