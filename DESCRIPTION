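Package: nfnirs
Title: Simulation and Energy-Ratio Analysis of fNIRS Neurofeedback Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing block-design
    functional near-infrared spectroscopy (fNIRS) neurofeedback training
    programmes for music performance anxiety self-regulation. Provides a
    session scheduler with seeded non-repeating stimulus assignment, a
    forward simulator of two-wavelength raw intensity recordings with
    known ground-truth hemodynamics (canonical double-gamma responses,
    physiological noise, drift and motion artifacts, and a session-wise
    learning profile), the full offline preprocessing chain (cropping,
    zero-phase FIR bandpass, Symlet-4 wavelet denoising, optical density
    conversion, modified Beer-Lambert inversion, demeaning and RMS
    normalisation), epoch-to-mean signal-energy ratio analysis with
    per-session trend classification, and a causal closed-loop thermometer
    feedback simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
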