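Package: optimammo
Title: Time-Domain Diffuse Optical Mammography Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-domain diffuse optical imaging of the
    compressed breast. Models picosecond-pulse transmittance through a
    homogeneous slab with the diffusion approximation (extrapolated boundary,
    image-source series), estimates localized lesion absorption contrast with
    the time-resolved modified Beer-Lambert law using a first-order Born mean
    partial pathlength for a spherical inclusion, and unmixes multi-wavelength
    absorption differences into oxy-/deoxy-hemoglobin, water, lipid and
    collagen concentration differences. Includes equal-count time gating,
    instrument-response convolution, homogeneous-property curve fitting,
    scan-to-map workflows, multivariate permutation tests on group means and
    variance-covariance matrices, Mann-Whitney and Pearson statistics, a
    Discrete AdaBoost classifier with Gini variable importance, a compiled
    Monte-Carlo photon-transport oracle, and synthetic phantom and cohort
    generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    MASS,
    jsonlite,
    EBImage,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
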