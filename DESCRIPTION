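Package: rhizosim
Title: Coupled Crop, Soil-Water and 3D Root-Architecture Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Field-scale simulation of cereal growth in which daily shoot
    carbon allocation limits root growth and local soil strength (a Busscher
    function of bulk density and water content) together with a Feddes-type
    water-status factor limits root elongation. Couples a light-use-efficiency
    (LINTUL-type) shoot engine and a multi-layer tipping-bucket soil water
    balance to either a stochastic 3D root architecture model or a simpler 1D
    conceptual root model, with feedback from root length density to water
    uptake and biomass growth. Ships deep-loosening versus control soil
    scenarios, a synthetic weather generator, weather-ensemble runs and
    virtual root-phenotype sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
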