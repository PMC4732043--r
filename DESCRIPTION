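Package: spama
Title: Spectral Filtering of Motion-Artifact Corrupted Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs heart rate and a surrogate pulse waveform from
    motion-artifact corrupted photoplethysmogram (PPG) recordings by
    comparing sliding-window power spectra of the PPG against simultaneous
    tri-axial accelerometer channels. Spectral peaks coherent with
    accelerometer activity are flagged as motion artifacts; the heart-rate
    fundamental is tracked across windows under a physiological continuity
    constraint, with hold-through and cubic-spline gap filling. Includes
    time- and frequency-domain heart-rate-variability analysis
    (SDNN, RMSSD, pNN50, LF/HF spectra), a Pan-Tompkins style ECG reference
    heart rate, error metrics against the reference, and a synthetic
    recording generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
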