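Package: springsat
Title: Carbonate Speciation, Mineral Saturation, and Carbon Isotope
    Evolution in Hot Spring Waters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling abiotic mineral precipitation in hot spring
    outflows. Implements carbonate-system speciation with Davies activity
    corrections and Plummer-Busenberg equilibrium constants, calcite and
    amorphous-silica saturation states, process trajectory models for CO2
    degassing at constant alkalinity, evaporation, and cooling, Rayleigh
    distillation of the carbon isotope composition of dissolved inorganic
    carbon with least-squares estimation of the fractionation factor, and a
    seeded generator of synthetic spring-transect and degassing-experiment
    datasets for end-to-end validation of the analysis chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
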