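Package: shapekf
Title: Denoising Multi-Replicate RNA SHAPE Reactivity Profiles by Kalman Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for extracting per-nucleotide reactivity signals from
    replicated RNA SHAPE (selective 2'-hydroxyl acylation analysed by primer
    extension) chemical-probing experiments under a log-normal measurement
    noise model. Provides preprocessing of reactivity profiles (background
    replacement of non-positive values, log/data domain transforms), box-plot
    based normalization, simulation of replicates with calibrated noise
    regimes, replicate combination by averaging, log-averaging, or a
    per-nucleotide scalar Kalman filter with a Gaussian log-domain prior, and
    evaluation statistics (log-domain RMS error, Matthews correlation
    coefficient between secondary structures, and the mean-versus-standard
    deviation heteroskedasticity diagnostic). Reads and writes two-column
    SHAPE reactivity files, CT files and dot-bracket strings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
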