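Package: glacialclim
Title: Downscaling and Ensemble Agreement Analysis of Last Glacial
    Maximum Climate Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prepares and audits Last Glacial Maximum (LGM) climate
    layers for biogeography and ecological niche modelling. Implements
    change-factor (delta) downscaling of general circulation model (GCM)
    output by ordinary kriging with a fitted spherical variogram,
    derivation of the 19 bioclimatic variables (BIO1-BIO19) from monthly
    temperature and precipitation, and quantification of between-GCM
    agreement: per-cell standard deviation and quartile coefficient of
    dispersion maps, latitudinal profiles, region summaries, correlation
    structure between models, and hierarchical grouping of GCMs by
    correlation distance. A synthetic pseudo-GCM ensemble generator with
    controlled spatial covariance, planted model groups and
    latitude-dependent disagreement makes every stage testable without
    climate-archive downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
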