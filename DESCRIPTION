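Package: plugadapt
Title: Simulation and Analysis of Sound-Localization Adaptation to Acute Monaural Plugging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how listeners re-weight acoustic localization
    cues after one ear is acutely plugged. Provides a Bayesian generative
    listener model (Gaussian spatial priors combined with noisy sensory
    likelihoods under maximum-a-posteriori or posterior-sampling decision
    rules, a sinusoidal head-shadow model of proximal sound level, and
    azimuth-dependent binaural weighting of spectral elevation cues) that
    simulates stimulus-response trial tables in double-polar coordinates;
    stimulus-response regression with gain, bias, correlation and error
    statistics; standardized multiple regressions quantifying the relative
    weights of proximal sound level, target azimuth and target elevation;
    windowed training-dynamics and azimuth-binned local-gain analyses; and a
    reproducible simulate-fit-report pipeline with exact one-sided sign tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
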