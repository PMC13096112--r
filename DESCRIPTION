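Package: stimvision
Title: Kinematic Ranking of Deep Brain Stimulation Programs from Hand-Aperture Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objective, within-session optimization of deep brain
    stimulation (DBS) programming from smartphone-derived hand-aperture
    kinematics. Segments repetitive hand opening-closing cycles from a 1-D
    aperture signal, computes a 23-parameter kinematic feature set (amplitude,
    speed, rhythm, variability, decrement), and ranks candidate stimulation
    programs against a stimulation-off baseline with a patient-specific
    Dynamically Weighted Improvement Score (DWIS) whose feature weights are
    proportional to across-program responsiveness, with an optional shrinkage
    toward uniform weights. Includes group-level inference (one-sample
    Wilcoxon tests with Benjamini-Hochberg correction, bootstrap median
    confidence intervals, linear mixed-effects concordance models against
    clinician ratings), a sparse principal-component decomposition of
    improvement matrices into kinematic domains with Tucker-congruence
    comparison between therapy cohorts, and seeded synthetic-cohort
    generators with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    lme4,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
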