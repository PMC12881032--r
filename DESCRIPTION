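Package: deltasim
Title: Scenario-Driven Integrated Simulation of Flooding, Salinity, Crops
    and Household Poverty in a Coastal Delta
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale integrated assessment model of a rural coastal
    delta. Generates contrasting mid-century scenario worlds and their
    transient drivers (sea-level rise, climate anomalies, Poisson cyclone
    event sets, population, economy, embankment maintenance, farming
    practice), couples a reduced-form flood model and its partial least
    squares / canonical correlation statistical emulator with a daily soil
    water and salt balance, FAO-style crop yield limitation factors, and a
    monthly microsimulation of archetypal households with coping-strategy
    optimisation. Computes headline livelihood indicators (inundated area,
    soil salinity, rice production, poverty rate, Gini index, GDP per
    capita), runs a one-at-a-time sensitivity ensemble and attributes
    poverty change to climatic versus non-climatic drivers by household
    group.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
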