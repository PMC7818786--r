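Package: fractalconn
Title: Complex-Wavelet Functional Connectivity for Scale-Free Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assessment of functional connectivity in the infraslow,
    arrhythmic (scale-free) regime of multivariate neural time series.
    Provides dual-tree complex wavelet estimators of the cross-spectrum and
    the derived connectivity indices (coherence, imaginary coherence and
    weighted phase lag index) together with their classical Fourier (Welch)
    counterparts, an exact circulant-embedding synthesizer of correlated and
    delayed bivariate fractional Gaussian noise / fractional Brownian motion
    with optional slow trends, wavelet-based Hurst exponent estimation, a
    Monte-Carlo harness for estimator bias and root-mean-square-error
    comparisons, and network-level statistics (density filtering by
    efficiency-cost optimization, paired group contrasts with false discovery
    rate control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
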