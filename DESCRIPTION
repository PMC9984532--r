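Package: sgakit
Title: Colony-Array Genetic Interaction Screens, Fluctuation Assays and
    Growth Curves for Yeast Genetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for synthetic genetic array (SGA)
    colony screens and companion assays in budding yeast. Reads colony-size
    tables from grid quantification tools, masks dummy borders, corrects
    per-plate spatial effects by median polish, normalizes to the plate
    median, scores double-mutant fitness under the multiplicative model,
    and calls synthetic-sick interactions with a replicate-exclusion rule,
    Welch t-tests and Benjamini-Hochberg adjustment. Also provides
    Luria-Delbrueck fluctuation-assay mutation-rate estimation via the
    Lea-Coulson median correction r = M(1.24 + ln M), exponential
    growth-curve fitting with population doubling times, hit-set
    intersection, linkage filtering, hypergeometric gene-set enrichment,
    and synthetic-data generators with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
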