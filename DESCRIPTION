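Package: dwmlis
Title: Line-Intersect Sampling Estimators for Downed Dead Wood Inventories
Version: 0.1.0
Authors@R:
    person("Forest", "Biometrics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Plot-level and population-level estimation of downed dead wood
    (coarse woody debris, fine woody debris, duff and litter) from
    line-intersect sampling field data organized in the relational schema
    used by the United States national forest inventory (FIA) down woody
    material tables. Provides the transect estimators for volume, biomass,
    carbon, cover and linear length with domain (species, decay class,
    forest type, condition) indicators, post-stratified population means
    and variances, reference lookups for bulk density and quadratic mean
    diameters, and a spatial Monte-Carlo simulator that generates synthetic
    stands with analytically known per-hectare truth for design-based
    validation of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
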