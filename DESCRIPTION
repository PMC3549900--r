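Package: osteofem
Title: Evolutionary Fracture-Probability Modelling of the Osteoporotic
    Proximal Femur
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the evolution of osteoporotic hip-fracture probability
    from clinical bone mineral density (BMD) trajectories. Densitometer
    readings are cross-calibrated to standardized BMD, converted to apparent
    density and Young's modulus through the Carter-Hayes cubic law, and fed
    into a linear-elastic tetrahedral finite element model of the proximal
    femur with Gruen-zone material mapping. Per-element equivalent strains
    drive a continuum damage model and a Paris-law based normalized fracture
    probability, stepped through time along fitted or synthetic BMD evolution
    curves (natural ageing or drug therapies). Includes a synthetic femur
    mesh generator, curve-fitting utilities with model selection, VTK export
    of damage and probability maps, and broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
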