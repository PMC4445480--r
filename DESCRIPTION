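Package: ketokin
Title: Kinetics and Neural-Network Modelling of Whole-Cell Enantioselective
    Ketone Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing batch-reactor progress curves of whole-cell
    enantioselective ketone reduction with isopropanol-coupled NADH
    regeneration. Simulates reversible reactor kinetics under both the
    pseudo-first-order mono-exponential approximation and the mass-action
    scheme consistent with the squared-product equilibrium constant; fits
    sampled progress curves to estimate equilibrium constants, conversions,
    and t95 times; computes enantiomeric excess; calibrates Hammett-type
    linear free-energy relationships among electronic descriptors; and trains
    a small from-scratch multilayer-perceptron regressor that predicts product
    concentration from initial loading, an electronic descriptor, and time,
    with sensitivity analysis, response curves, and leave-one-substrate-out
    external validation. A seeded synthetic-data generator emulates the
    9-substrate, 22-run reactor study design so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
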