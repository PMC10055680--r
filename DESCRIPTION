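Package: mrfmap
Title: 3D MR Fingerprinting Simulation, Dictionary Matching and Repeatability Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Extended phase graph (EPG) simulation of an inversion-prepared
    FISP/FLASH/T1rho-prepared MR fingerprinting sequence, geometric-grid
    dictionary generation with SVD subspace compression, and voxelwise
    pattern matching producing proton density, T1, T2, T1rho and B1 maps.
    Includes digital phantoms (NIST-like sphere layouts and brain-like
    tissue compartments), direct and radial stack-of-stars k-space
    simulation with golden-angle spoke tables, adjoint non-uniform DFT
    reconstruction, and the evaluation statistics used in quantitative
    relaxometry repeatability studies (ROI summaries, intraclass
    correlation, Bland-Altman limits of agreement, paired t-tests, SNR).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
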