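Package: oleofeed
Title: Feed-Strategy Planning and Kinetic Analysis of Fed-Batch Lipid
    Production with Oleaginous Yeasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and evaluating carbon-source feeding
    strategies in fed-batch cultivations of oleaginous yeasts such as
    Saitozyma podzolica. Covers restock-to-target and calculated
    reduced-excess pulse feeding, continuous-feed pump-rate and
    dilution-rate computation, phase-resolved yield and volumetric-rate
    accounting, four-parameter logistic smoothing of cumulative time
    courses with analytic-derivative rate curves, and an approximate
    carbon mass balance over CO2, lipid-free cell mass, lipids, organic
    acids and residual sugar. A fed-batch bioreactor simulator with
    Monod growth, nitrogen-limitation-triggered lipid accumulation and
    sugar-excess-dependent organic-acid formation generates realistic
    cultivation records for testing and method development.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
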