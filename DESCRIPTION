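Package: fermkin
Title: Batch Alcoholic Fermentation Kinetics with Byproduct Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and calibration of a modified Monod model for batch
    alcoholic fermentation in which accumulated byproducts (glycerol, acetic
    and succinic acid, treated as one lumped concentration) inhibit yeast
    growth. Provides the coupled biomass-substrate-ethanol-byproduct rate
    equations with yield-coefficient stoichiometry, a Luong-type family of
    inhibition laws (linear, parabolic, power-law exponential), a fixed-step
    fourth-order Runge-Kutta integrator, nonlinear least-squares calibration
    of the inhibition function with family selection, yield-coefficient
    estimation from endpoint data, model-comparison statistics (MSE, RMSE,
    average absolute deviation, R-squared, fermentation-time delay), and
    seeded synthetic-data generators for testing the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
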