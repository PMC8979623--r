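Package: pvztools
Title: Composite Pulmonary Vascular Impedance from Asynchronous Pressure
    and Doppler Captures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts asynchronous screen captures of pulmonary-artery
    pressure traces and pulsed-wave Doppler velocity spectrograms (each with
    an ECG strip) into composite pulmonary vascular impedance (PVZ) spectra
    and derived right-ventricular afterload parameters: total pulmonary
    resistance (TPR), characteristic impedance (Zc) and the stiffness index
    (Zs).  Provides automated border detection for line traces and Doppler
    frequency envelopes, pixel-to-physical axis calibration, 1000 Hz
    resampling, ECG R-peak detection and R-R beat segmentation, average
    representative beat construction, Fourier harmonic decomposition, and
    harmonic-index impedance spectra.  A synthetic-fixture generator
    (three-element Windkessel pressure, half-sine flow pulses, synthetic
    ECG, rendered screen-capture images) supplies analytic ground truth for
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jpeg,
    jsonlite,
    png,
    rlang,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
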