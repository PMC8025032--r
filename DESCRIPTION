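Package: pactangio
Title: Quantification of Tumor-Associated Microvasculature in Photoacoustic Breast Angiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of photoacoustic computed
    tomography (PACT) breast angiograms aimed at assessing tumor change
    during neoadjuvant chemotherapy. Includes a breast-mimicking inclusion
    phantom and synthetic vascular-scene generator, a desk-scale full-ring
    photoacoustic forward model with universal back-projection
    reconstruction and depth compensation, angiogram conditioning
    (denoising, Hessian-based Frangi vesselness, blending, background
    thresholding), skeleton-based relative vessel density mapping, windowed
    image entropy, rotational-SVD directionality and anisotropy, an
    anisotropy-weighted entropy map with automatic lesion segmentation, and
    region-of-interest versus healthy-tissue statistics based on one-tailed
    Welch t-tests over non-overlapping windows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    methods,
    tiff,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
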