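Package: papeors
Title: Photoacoustic Polarization-Enhanced Optical Rotation Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of chiral-molecule optical rotation and concentration
    from photoacoustic (PA) time-series signals recorded in trans-illumination
    geometry. Provides a synthetic PA-signal forward model (Beer-Lambert
    fluence decay with a Malus-law cos-squared rotation factor, band-limited
    transducer convolution, noise and pulse-energy jitter), Chebyshev bandpass
    filtering, pulse-energy normalization, Wiener deconvolution of the
    transducer impulse response, speed-of-sound calibration and time-to-depth
    mapping, Malus-law inversion of envelope amplitude ratios, piecewise
    quadratic and linear calibration regression, and Clarke Error Grid
    Analysis with limit-of-detection and repeatability summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
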