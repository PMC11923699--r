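Package: geofalter
Title: Model-Based Geostatistical Mapping of Childhood Growth Faltering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits linear geostatistical models to continuous anthropometric
    z-scores observed at GPS-located survey clusters, with a stationary
    Gaussian process (exponential correlation) capturing residual spatial
    variation and a Gaussian nugget for individual-level variation.
    Supports selection of lagged prenatal environmental covariates by AIC,
    plug-in kriging of the latent surface on a regular grid, conversion of
    predictive z-score distributions to prevalence of stunting, underweight
    and wasting (probability of a z-score below -2), expected case counts
    from a gridded under-5 population, and population-weighted aggregation
    to administrative polygons. Includes a synthetic survey generator so the
    whole pipeline is testable without restricted-access survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
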