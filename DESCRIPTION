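Package: seldiprep
Title: Adaptive Preprocessing of SELDI-TOF Mass Spectra Under a Quadratic
    Variance Noise Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Preprocessing of low-resolution SELDI-TOF/MALDI protein mass
    spectra driven by an empirical model of the detector: intensity
    fluctuations follow a natural exponential family whose variance is a
    quadratic function of the mean (NEF-QVF), with the quadratic variance
    function estimated from replicate matrix-only ("buffer") spectra.
    Provides pointwise moment estimation and quadratic variance fitting,
    heteroscedastic wavelet shrinkage of the mean spectrum in an orthogonal
    Symmlet-8 basis with per-coefficient noise variances obtained by pushing
    the clamped variance function through the squared transform matrix,
    combined baseline removal (monotone cubic interpolation through local
    minima) and peak detection with area-based thresholding, a hybrid
    test-data simulator (virtual-protein clean spectra plus QVF buffer
    noise), and FDR/TPR operating-characteristic evaluation with normalized
    partial-AUC scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mzR
Config/testthat/edition: 3
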