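Package: rinoise
Title: Race-in-Noise Psychophysics and Bayes Factor ERP Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the race-in-noise paradigm: parametric phase-coherence
    degradation of face stimuli with amplitude-spectrum preservation, default
    Jeffreys-Zellner-Siow (JZS) Bayes factors for paired designs, a behavioral
    pipeline for the other-race categorization advantage (trial filtering,
    condition means, per-coherence Bayes factor contrasts, signal detection
    analysis, bootstrap intervals), a sample-wise mass-univariate Bayes factor
    ERP pipeline (band-pass filtering, baseline correction, common-average
    referencing, artifact rejection, spherical-spline channel interpolation,
    electrode-cluster scans, evidence-window extraction, Bayes factor
    topographies), and a synthetic-data generator with known ground truth for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    png,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
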