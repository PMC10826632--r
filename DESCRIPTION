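Package: dwimotion
Title: Head Motion Correction for Diffusion MRI by Leave-One-Out q-Space
    Signal Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for correcting bulk head motion in diffusion-weighted MRI
    series sampled on arbitrary q-space schemes (multi-shell, Cartesian grid,
    or sparse random Cartesian). For each diffusion-weighted volume an
    L2-regularized 3dSHORE basis is fit to all other volumes and the predicted
    signal at the left-out q-space point serves as the registration target for
    a rigid or affine alignment, iterated up to twice (the SHORELine scheme).
    Includes a multi-tensor digital phantom that renders motion-corrupted
    series with known ground-truth per-volume rigid transforms, Marchenko-
    Pastur PCA denoising, quality metrics (motion-parameter error summaries,
    neighboring-DWI correlation, FWHM smoothness), and a factorial benchmark
    harness for evaluating correction accuracy against simulated truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
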