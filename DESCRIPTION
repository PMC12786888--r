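Package: glcmface
Title: Grey-Level Co-Occurrence Texture Scoring of Facial Erythema
Version: 0.1.0
Authors@R: person("glcmface", "maintainers", email = "maintainers@glcmface.org",
    role = c("aut", "cre"))
Description: Quantitative assessment of facial erythema from cross-polarized
    photographs. Builds grey-level co-occurrence matrices (GLCM, 256 grey
    levels, horizontal offset d = 1) over four facial regions of interest
    (left cheek, right cheek, nose, chin), computes the contrast and
    homogeneity texture features, and aggregates them into weighted
    whole-face scores (0.35/0.35/0.15/0.15). Provides the clinical
    statistics layer used in longitudinal phototherapy studies: Clinician
    Erythema Assessment (CEA) score handling and complete-agreement
    analysis, per-session treatment-energy summaries, Friedman rank tests
    with Dunn post hoc comparisons, Spearman rank correlation with
    t-distribution inference, and percent-change summaries. A deterministic
    synthetic-study generator renders face images with spatially clustered
    erythema lesions and telangiectasia responding to treatment across
    three timepoints, plus noisy three-rater ordinal gradings, so the whole
    pipeline is testable without clinical image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
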