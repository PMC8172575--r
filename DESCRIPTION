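Package: abbrmeta
Title: Harmonization of Medical Abbreviation Sense Inventories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds concept-oriented meta-inventories of medical
    abbreviations from multiple source sense inventories. Provides lexical
    normalization of short and long forms, non-semantic unique identifier
    assignment, string-similarity blocking and candidate generation,
    gradient-boosted classification of synonymous long-form pairs,
    connected-component synonym grouping, rule-based quality-control
    heuristics with a modify/retire workflow, inventory summary statistics,
    and macro/micro coverage evaluation against annotated clinical text.
    Includes a synthetic-fixture generator with ground-truth synonym
    structure so every pipeline stage can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    stringi,
    igraph,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
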