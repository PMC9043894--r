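Package: btdecay
Title: Degradation Kinetics of Bt Cry Proteins in Soil
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits first-order (Y = a*exp(-b*X)) and plateau
    (Y = Y0 + a*exp(-b*X)) degradation models to time-course protein
    residue measurements in soil, derives DT50 half-lives and
    goodness-of-fit statistics, compares the two nested models, runs a
    split-plot repeated-measures ANOVA with Greenhouse-Geisser
    correction and polynomial time contrasts over a factorial design
    (soil site, temperature, water content, sterilization), and ranks
    environmental factors by their influence on early-stage (DT50) and
    late-stage (plateau Y0) degradation. Includes a synthetic-data
    generator emulating a 36-condition, 18-time-point, triplicate
    laboratory incubation so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
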