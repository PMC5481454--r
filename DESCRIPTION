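Package: adctexture
Title: Sensitivity of Haralick Texture Features from ADC Maps to Imaging
    and Pre-Processing Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates diffusion-weighted MRI phantoms, fits apparent
    diffusion coefficient (ADC) maps by log-linear regression over
    b-values, quantizes region-of-interest intensities to gray levels,
    builds symmetric directionally independent gray-level co-occurrence
    matrices (GLCMs), computes 19 Haralick texture features, and
    quantifies how feature distributions shift under one-at-a-time
    changes of resolution, noise, b-value combination, gray-level count
    and quantization method, using pairwise two-sample
    Kolmogorov-Smirnov tests with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
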