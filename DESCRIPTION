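Package: kumamotoscale
Title: Revised and Original Kumamoto Scale Scoring for Hereditary
    Transthyretin Amyloidosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic clinimetric scoring of the Kumamoto scale for
    hereditary transthyretin (ATTRv) amyloidosis. Converts structured
    per-visit clinical findings (anatomical levels of sensory loss, MRC
    muscle grades, autonomic measurements, cardiac and renal findings)
    into item scores, four 0-24 subdomain scores and a 0-96 total, under
    both the revised scale and the original 1997 scale for longitudinal
    comparability. Includes side-by-side scale comparison, multi-visit
    trajectories with progression evaluation per the Swedish guideline
    rule, a modified body mass index helper, JSON/CSV readers and writers
    with exhaustive validation, and a seeded synthetic-cohort simulator
    for testing scoring paths and quantifying the revised scale's
    granularity advantage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
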