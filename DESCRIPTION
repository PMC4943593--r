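Package: wetlandCH4
Title: Wetland Methane Flux Projection with an Empirical Water-Table Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Projects daily and regional methane (CH4) emissions from temperate
    freshwater marshes through the 21st century. Couples a stochastic RCP-style
    weather and CO2 scenario generator, an empirical bucket water-table model
    with Priestley-Taylor evapotranspiration and a freeze-season rule, an
    empirical climate/CO2 response function for above-ground net primary
    productivity, and a daily substrate-based CH4 production, oxidation and
    transport model with Q10 temperature control, soil-texture and redox (Eh)
    modifiers. Includes bounded-search calibration of the hydrological
    parameters, validation statistics (observed-versus-simulated regression,
    linear trends), and regional aggregation with wetland-area restoration
    scenarios and CO2-equivalent conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lhs,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
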