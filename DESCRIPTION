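Package: cmjkit
Title: Countermovement-Jump Force-Time Analysis with Statistical
    Parametric Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trial-level processing of dual-force-plate countermovement
    jump (CMJ) recordings: body-weight estimation, movement-onset
    detection by threshold and backtracking methods, take-off detection,
    quality-control screening, impulse-momentum kinetics with
    unweighting/braking/propulsion phase segmentation, discrete per-limb
    metrics (net impulse, net peak force, jump height, contraction time,
    modified reactive strength index, interlimb asymmetry indices), and
    one-dimensional statistical parametric mapping (SPM) of time-normalized
    force waveforms with random-field-theory thresholds, suprathreshold
    cluster inference and a sign-flip permutation oracle.  Includes a
    synthetic dual-plate cohort generator with injectable involved-limb
    force deficits so the full pre/post comparison design can be exercised
    and calibrated without confidential athlete data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    patchwork,
    pracma,
    rlang,
    stats,
    utils,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
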