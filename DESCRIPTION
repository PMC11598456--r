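Package: gaitstab
Title: Margin of Gait Stability from Six-DoF Pelvis Motion
Version: 0.1.0
Authors@R:
    person("gaitstab", "developers", email = "gaitstab@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying dynamic gait stability from optical
    motion-capture marker data. Computes the extrapolated centre of mass
    (XCoM) and the margin of stability (MoS) in the mediolateral and
    anterior directions from a three-marker pelvis model, extracts
    step-normalised six-axis pelvic velocity features (a "virtual IMU"),
    and estimates per-step critical MoS values with supervised principal
    motion analysis, a partial-least-squares-style regression on
    multivariate gait waveforms, including cross-validated selection of
    the number of principal motions. Ships an analytic gait simulator and
    a latent-factor feature generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
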