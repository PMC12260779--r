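Package: pbct
Title: Propagation-Based Phase-Contrast Breast CT: Simulation, Reconstruction and Image-Quality Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for low-dose propagation-based phase-contrast computed tomography
    (PB-CT) of the breast. Simulates parallel-beam acquisition of voxelized breast
    phantoms (contact, transport-of-intensity and Fresnel forward models with Poisson
    photon noise, flat and dark fields), performs flat/dark correction and TIE-Hom
    (Paganin) single-image phase retrieval, and reconstructs slices with filtered back
    projection, regularized direct-Fourier gridding, and a customized SART with
    relaxation scheduling, random projection ordering and periodic 3D bilateral
    filtering. Includes the objective image-quality suite (contrast, SNR, CNR,
    noise-based spatial resolution, noise power spectrum, intrinsic quality), the
    cSART parameter-tuning procedure, calcification-preserving thick-slice rebinning
    with 12-bit mapping and DICOM export, and reader-study statistics (paired t-tests
    with Bonferroni correction, two-way ICC, Cronbach's alpha, visual grading
    characteristics AUC with two-level bootstrap).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
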