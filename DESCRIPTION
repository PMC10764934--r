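Package: capdyn
Title: Co-Activation Pattern Dynamics for Multi-Subject ROI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies transient brain states (co-activation patterns, CAPs)
    from multi-subject region-of-interest fMRI time series by temporal k-means
    clustering with a correlation distance, and characterises their dynamics as
    a discrete Markov chain: dwell times, occurrence rates, directional
    transition probabilities, and the entropy of Markov trajectories between
    states. Provides covariate-adjusted group contrasts with Benjamini-Hochberg
    false-discovery-rate control within metric families, partial correlations
    with symptom scores, nested cross-validated support-vector-machine
    classification with permutation testing, and a synthetic hidden-Markov
    cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
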