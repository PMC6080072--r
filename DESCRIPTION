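Package: ddlibs
Title: Data-Driven Calibration for Laser-Induced Breakdown Spectroscopy
Version: 0.1.0
Authors@R:
    person("LIBS", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies an element (potassium, via its resonance doublet at
    766.57 and 769.95 nm) from laser-induced breakdown spectra.  Spectra are
    decomposed with an oversampled, approximately shift-invariant
    higher-density discrete wavelet transform built from a three-channel
    perfect-reconstruction filter bank; the most concentration-informative
    wavelet coefficient is selected by a bagged random-frog search; and the
    final calibration is a partial-least-squares regression.  Includes a
    synthetic spectrum simulator (peak shift, broadening, laser-energy
    fluctuation, self-absorption, baseline, noise and interfering matrix
    lines), univariate peak calibration, cross-validation and figure-of-merit
    utilities, a method-comparison harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
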