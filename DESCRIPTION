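Package: cvccost
Title: Labor-Cost Decision Model for Central Venous Catheter Confirmation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-tree labor-cost model comparing chest-radiograph
    (protocol A) and point-of-care ultrasound (protocol B) confirmation of
    central venous catheter position. Provides itemized per-patient cost
    breakdowns built from wage rates and task times, complication-driven
    diversion costing, hospital- and national-scale projections, one-way and
    two-way deterministic sensitivity analysis with tornado ordering,
    break-even (threshold) analysis, and Monte-Carlo probabilistic
    sensitivity analysis with a built-in parameter-draw generator and a
    library of published complication-probability scenarios.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
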