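Package: metstab
Title: Stability Analysis for Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Yield-stability analysis for plant-breeding multi-environment
    trials (METs) laid out as augmented designs with replicated check
    cultivars. Computes the classical univariate stability indices
    (environmental variance, coefficient of variation, Wricke's ecovalence,
    Shukla's stability variance, Finlay-Wilkinson joint-regression slope,
    Eberhart-Russell deviation from regression, coefficient of
    determination), aggregates them into a single harmonic-mean rank score
    (SID/RSID), and fits the AMMI and GGE singular-value decompositions with
    a combined analysis of variance, which-won-where sectoring,
    index-correlation and two-way heatmap clustering. A seeded synthetic MET
    generator with known ground truth supports validation and worked
    examples without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
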