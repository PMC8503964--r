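Package: contrastfade
Title: Simulation and Analysis of Contrast-Adaptation Matching Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for method-of-adjustment contrast matching
    experiments on sinusoidal luminance gratings. Renders Gabor-like grating
    stimuli in degrees of visual angle, builds the logarithmically spaced
    contrast scales backing a 1000-step matching slider (including the
    randomly rotated exercise variant), constructs balanced trial plans for
    control and adaptation sessions, runs them against a generative lognormal
    simulated observer, and analyses trial records with pooled log-log
    ordinary least squares and a random-intercept linear mixed model fitted
    by profiled maximum likelihood. Includes a packaged table of per-observer
    mean contrast matches for desk replication of the reference analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    lme4,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
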