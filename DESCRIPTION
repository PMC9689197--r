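Package: spinemult
Title: Sitting-Height Multipliers for Predicting Spinal Growth at Maturity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the sitting-height multiplier method for predicting
    spinal growth at skeletal maturity. Ships the published monthly age- and
    sex-specific sitting-height multiplier tables and the clinical formulas
    built on them: predicted mature sitting height, single-vertebra height,
    growth remaining in a spine segment, growth lost to arthrodesis, the
    Vitruvian limb-lengthening target used in achondroplasia planning, and
    mature standing-height estimation. Also provides the derivation machinery
    that produces multiplier tables from percentile-structured growth
    references (M = Lm/L), cross-percentile variability statistics, polynomial
    regression comparison of multiplier sets across reference databases, a
    synthetic growth-reference generator with known ground truth, CSV readers
    and writers for both table dialects, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
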