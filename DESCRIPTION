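Package: vsmra
Title: Velocity-Selective MR Angiography Pulse Design and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Design and Bloch-equation simulation of velocity-selective (VS)
    magnetization-prepared non-contrast MR angiography of the neck. Builds
    the double-refocused VS saturation pulse with B0/B1 field-error
    pre-compensation, the adiabatic hyperbolic-secant slab-selective
    inversion, calibration of compensation parameters and ECG trigger delays
    from field maps and phase-contrast flow curves, center-out square-spiral
    segmented k-space scheduling, and an ECG-gated protocol simulator on a
    digital neck phantom scored by the relative artery-to-muscle contrast
    ratio.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
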