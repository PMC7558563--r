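Package: phsdyn
Title: Predicted Heat Strain with Dynamic Clothing Corrections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Minute-by-minute simulation of the Predicted Heat Strain (PHS)
    human heat-balance model (ISO 7933:2004 program structure) with
    interchangeable algorithms for correcting static clothing insulation and
    evaporative resistance for the pumping effects of wind and body movement:
    the ISO 7933 coefficients, the ISO 9920 formulas for normal, cold-weather
    and light clothing, and Lu's regression for light clothing. Supports a
    measured walking-speed input as an alternative to the metabolic-rate
    estimate, computes duration-limited exposure times from rectal temperature
    and dehydration, builds algorithm-comparison grids of dynamic insulation
    and evaporative resistance, evaluates predictions against observed
    physiological series by rmsd and bias, and generates synthetic observed
    series with autocorrelated measurement noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
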