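Package: carabidscape
Title: Agent-Based Simulation of Carabid Beetle Populations in Dynamic
    Agricultural Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatially explicit, daily time-step simulation of a
    spring-breeding carabid beetle (Bembidion lampros) in synthetic
    agricultural landscapes, built to evaluate pesticide-policy mitigation
    measures. Generates raster landscapes with farms, crop rotations and
    dated management events; models insecticide application, spray drift,
    temperature-dependent environmental decay and threshold-trigger
    mortality in toxic units; tracks super-individual beetle agents through
    development, movement, reproduction, density dependence and
    overwintering; extracts density, occupancy and abundance endpoints and
    abundance-occupancy (AOR) changes across mitigation scenarios; and fits
    backward-stepwise AIC regressions of endpoints on landscape
    heterogeneity metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
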