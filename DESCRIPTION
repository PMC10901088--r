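Package: bforient
Title: Orientation Estimation for Neural Sources with LCMV Beamformers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for comparing scalar linearly
    constrained minimum variance (LCMV) beamformers -- Unit-Gain,
    Unit-Noise-Gain and Array-Gain -- at estimating the orientation of a
    dipolar neural source from EEG, MEG or combined EEG-MEG sensor data.
    Provides leadfield input/output and SVD-derived tangential/radial
    target coordinate frames, synthetic leadfield and sensor-data
    generators with controlled singular spectra and noise levels,
    covariance estimation with trace-scaled regularization, the three
    orientation eigenproblems, EEG-MEG fusion, closed-form expressions for
    the Unit-Gain orientation bias (high-noise and low-noise limits via
    the rank-one secular equation), pseudo-Z and neural-activity-index
    scores with their pre-whitening equivalences, and seeded Monte-Carlo
    experiment drivers producing tidy error tables with summary
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
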