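Package: blendopt
Title: Characterization and Optimization of Binary Vegetable Oil Blends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for characterizing and optimizing binary vegetable oil
    blends from per-sample measurement tables. Computes fatty-acid nutritional
    indices (atherogenicity, thrombogenicity, hypocholesterolaemic ratio,
    omega-6/omega-3 ratio), oxidation status (TOTOX), CIE76 colour difference,
    and sensory acceptability scores; fits a small multilayer-perceptron
    surrogate mapping blend shares to 28 measured characteristics; performs
    weight-based (Yoon) sensitivity analysis of the trained network; and
    solves a constrained, group-weighted grid optimization that finds the
    blend composition closest to a reference oil subject to minimum sensory
    scores. Ships the measurement tables of a sunflower/flaxseed blending
    study as a packaged dataset and a synthetic binary-mixing generator for
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
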