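Package: gazethreat
Title: Signal-Detection Models of Gaze-Emotion Integration in Threat Perception
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing two-alternative anger/fear categorisation of
    morphed facial expressions presented with direct or averted gaze. Builds
    balanced trial schedules for the 2 (gaze) x 2 (emotion) x 7 (morph
    intensity) design, fits competing probit choice models per observer
    (threat-congruent perceptual sensitivity, gaze-conditioned decision bias,
    and their combination) by maximum likelihood, compares models at the group
    level with fixed-effects Bayes factors and random-effects Bayesian model
    selection with exceedance probabilities, and provides accuracy
    aggregation, exclusion filtering, threat-congruence contrasts and the
    associated paired tests. A synthetic-cohort generator simulates observers
    under each model so that model and parameter recovery can be studied
    without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
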