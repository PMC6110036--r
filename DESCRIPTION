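Package: vesselmorph
Title: Vessel Histomorphometry and Multi-Criteria Efficacy Ranking for
    Intimal-Hyperplasia Studies
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis pipeline for balloon-injury intimal
    hyperplasia experiments: computes media/intima areas and thicknesses
    (MA, IA, MT, IT) and hyperplasia ratios (HRIA, HRIT) from nested
    vessel cross-section contours, quantifies protein expression from
    integrated optical density (IOD) measurements (immunohistochemistry
    fields and Western-blot bands normalized to beta-actin), performs
    one-way ANOVA with reference-group post-hoc comparisons, and ranks
    treatment efficacy by single-factor fuzzy comprehensive evaluation
    using the TOPSIS closeness grade. A seeded synthetic-cohort
    generator emulates the nine-group rat study design so the full
    pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
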