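Package: resppair
Title: Paired Respiratory Surrogate Signal Analysis for 4D CT and Gated
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("Fox", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying discrepancies between two simultaneously
    recorded respiratory surrogate signals (an optical marker-displacement
    trace and an abdominal pressure-belt trace) and for propagating those
    discrepancies through local-amplitude phase sorting into per-phase
    anatomy and gating-window mismatch.  Includes a synthetic breathing
    generator with controllable phase lag, limb-shape warping and noise, a
    digital diaphragm motion phantom, readers and writers for simple
    text dialects of the two vendor trace formats, extrema detection and
    cycle segmentation, phase-shift estimation by end-of-inhale latency and
    by direct least-squares ellipse fitting, average breathing-cycle shape
    comparison, ten-phase local amplitude sorting, and gating duty-cycle
    overlap analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
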