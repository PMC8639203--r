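Package: vestscreen
Title: Test Batteries and Sequential Diagnostic Algorithms for Chronic
    Vestibular Syndromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives screening test batteries and ordered threshold-rule
    diagnostic algorithms for chronic vestibular syndromes (persistent
    postural-perceptual dizziness, chronic dizziness due to anxiety,
    unilateral vestibular hypofunction, undifferentiated dizziness).
    Implements instrument-level asymmetry indices (Jongkees canal paresis,
    directional preponderance, VEMP interaural asymmetry, video head
    impulse test gain asymmetry), questionnaire score validation,
    Kruskal-Wallis screening with Dunn-Bonferroni post-hoc comparisons,
    ROC/Youden-index threshold derivation with DeLong confidence
    intervals, and construction and evaluation of six sequential
    rule-based classifiers. A seeded synthetic-cohort generator emulates
    published group-level summary statistics and per-item missingness so
    the whole pipeline is reproducible without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
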