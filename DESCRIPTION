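Package: feedenergy
Title: Digestible and Metabolizable Energy Evaluation of Swine Feed Ingredients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for total-collection digestion trials in growing pigs:
    nutrient-composition algebra on as-fed and dry-matter bases, diet
    formulation and replacement geometry, per-animal digestible (DE) and
    metabolizable energy (ME) and apparent total tract digestibility (ATTD)
    from balance records, direct- and difference-method ingredient
    evaluation, design-aware least-squares means for Youden-square trials,
    Pearson correlation screening, stepwise construction and application of
    DE/ME prediction equations, and a synthetic-trial generator for
    parameter-recovery validation of the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
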