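Package: nirtransfer
Title: Calibration Transfer Between Near-Infrared Spectrometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for transferring multivariate calibration models between
    near-infrared spectrometers with different wavelength grids and
    resolutions. Implements spectral pretreatments (moving-average smoothing,
    standard normal variate, mean normalization), Kennard-Stone sample
    selection, partial least squares and least-squares support-vector-machine
    regression, Passing-Bablok method-comparison regression for
    master-instrument selection, piecewise direct standardization (PDS), and
    a linear-interpolation PDS variant that resamples the slave instrument
    onto the master wavelength grid before the per-channel transfer
    regression. A seeded simulator of paired dual-instrument fruit spectra
    supports end-to-end validation without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
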