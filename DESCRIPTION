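Package: mslquant
Title: Multimodal Physiological Quantification of Motion Sickness Level
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying motion sickness level (MSL)
    from multi-rate physiological and behavioral recordings: reconstruction of
    fragmented, jittered sensor timelines onto rate-exact sample grids;
    per-sensor preprocessing chains (spectral notch, zero-phase band-pass,
    conductance conversion, common average reference); a windowed feature
    engine covering PPG heart-rate-variability and Poincare indices,
    electrodermal tonic/phasic decomposition, EEG band power, power ratios and
    functional-network connectivity (coherence, phase locking value), eye
    closure/gaze and head kinematic descriptors; questionnaire scoring (SSQ,
    FMS, MSSQ with percentile mapping, Film IEQ); repeated-measures
    correlation with smallest-effect-size-of-interest tiers and
    Benjamini-Hochberg families; and an additive-boosting contribution
    analysis with sensor-domain ablation. A synthetic-cohort generator with
    planted signal-MSL associations makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    car
Config/testthat/edition: 3
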