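Package: phenoforge
Title: Degree-Day Phenology, Climate Suitability and Pest Forecast Tools
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Engines for temperature-driven pest risk analysis: daily
    degree-day calculation from minimum/maximum temperatures (simple
    average, single sine and single triangle methods with horizontal or
    vertical upper-threshold cutoffs), multi-stage insect phenology
    timelines with event markers, voltinism (generations-per-year)
    mapping, lethal-cold climate suitability across years, condition
    day-count and precipitation analytics, plant hardiness zone banding,
    30-day forecast assembly that stitches observed weather, a short-term
    forecast and a daily climatology, and a seeded synthetic daily
    weather generator so every analytic is testable without external
    data. Pest parameters are supplied through plain-text profile files;
    a command-line front end drives the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'degree-days.R'
    'weather-io.R'
    'synthetic-weather.R'
    'phenology.R'
    'climate-analytics.R'
    'pestcast.R'
    'profiles.R'
    'cli.R'
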