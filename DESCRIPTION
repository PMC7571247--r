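Package: wavemap
Title: Response Mapping for Wavelet Denoising Parameter Selection
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A recommendation system for choosing wavelet-denoising settings
    for biomedical signals and images. Sweeps wavelet family (Daubechies,
    Symlet, Coiflet) by filter order, decomposition level and noise intensity
    on 1D signals and 2D grayscale images, denoises with Donoho's universal
    global threshold, scores each setting against a gold standard (MSE,
    Pearson correlation, Euclidean distance, PSNR), and assembles the scores
    into spatial (level x order) response maps and volumetric 4D response
    tensors from which optimal settings, maximum-achievable-quality curves
    and wavelet-family robustness statistics (Chi-squared normality
    screening, Mann-Whitney comparisons) are derived. Includes noise models
    (additive white Gaussian, impulse, salt-and-pepper, multiplicative
    speckle, composite schedules) and generators for CT-like, MR-like and
    EMG-like synthetic gold standards.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    tiff,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
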