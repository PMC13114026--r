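Package: sevoEEG
Title: Quantifying Anesthetic Depth in Mouse EEG: Burst Suppression,
    Multitaper Spectra, Theta Topography, and Behavioral Endpoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the electroencephalographic and
    behavioral response of mice to stepped volatile-anesthetic
    (sevoflurane) exposure. Implements amplitude/duration-based
    burst-suppression segmentation with the burst-suppression ratio (BSR)
    and suppression-onset concentration, multitaper (DPSS) density
    spectral arrays with group-median aggregation, theta-band (4-8 Hz)
    topographic mapping on the six-site mouse montage with a scalar
    anteriorization index, ascending (MAC-type) and descending
    (righting-reflex) staircase endpoint protocols and estimators, and
    the gated two-sample comparison rule (Student's t after
    normality/homogeneity gates, Mann-Whitney otherwise). A
    strain-parameterized synthetic cohort generator with per-sample
    ground truth makes every stage of the pipeline testable without
    access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
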