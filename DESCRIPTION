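Package: pfastk
Title: Transgenerational Toxicokinetic Modeling of PFOA for Drinking-Water Guidance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-compartment daily-timestep toxicokinetic model of
    perfluorooctanoate (PFOA) serum concentrations across a mother-infant
    pair exposed through drinking water. Simulates placental transfer at
    birth, lactational transfer with maternal mass balance, age-specific
    intake rates, body weights and volume-of-distribution adjustment, and
    derives drinking-water health-based guidance values: reference serum
    concentration, reference dose, relative source contribution, iterative
    guidance-value solver, and an additive health risk index. Includes
    model-evaluation workflows against paired maternal/infant serum tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
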