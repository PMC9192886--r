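Package: spectboost
Title: Deep-Learning Enhancement of Fast Low-Count Bone SPECT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Synthesizes standard-scan-time bone SPECT volumes from 1/7
    scan-time acquisitions plus a co-registered CT, using a nested-U
    ("U-squared") convolutional generator built from residual U-blocks,
    trained with a lesion-attention composite loss (L1 + SSIM, with an
    extra weight on physician- or simulator-provided lesion regions) under
    deep supervision. Includes a synthetic NEMA IEC body-phantom and
    subject simulator (Gaussian point-spread blur plus Poisson counts
    proportional to scan time), NIfTI volume I/O with world-coordinate
    resampling of CT to the SPECT grid, and a quantitative evaluation
    suite (PSNR, SSIM, SUVmax/SUVmean per sphere, Rose-criterion
    detectability, difference maps), so the full train/enhance/evaluate
    workflow runs at desk scale without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
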