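Package: mumri
Title: Muscle Twitch Dynamics and Fatigue Recovery from Dynamic MRI
Version: 0.1.0
Authors@R: person("MUMRI", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise analysis of stimulated dynamic muscle MRI. Extracts
    twitch timing landmarks (onset, first minimum, baseline return, second
    minimum) from pulsed-gradient spin-echo latency series, builds parametric
    maps, histograms and thresholded category maps of rise, contraction and
    half-relaxation times, and quantifies post-exercise recovery of twitch
    peak velocity from cyclic phase-contrast series with a modified Gompertz
    model. Includes a forward-model phantom generator with exact analytic
    ground truth, minimal NIfTI-1 input/output, stimulation-current
    selection, series registration, repeatability and group-comparison
    utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
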