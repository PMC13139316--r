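Package: calcmorph
Title: Morphometry and Coupling Analysis of Vascular Calcification Clusters in CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments calcific clusters from three-dimensional CT attenuation
    volumes (Hounsfield-unit thresholding, morphological cleaning, 3D
    connected-component labeling), extracts per-cluster geometric and density
    descriptors (volume, oriented-bounding-box dimensions, aspect ratio,
    eccentricity, compactness, mean attenuation and attenuation
    heterogeneity), and analyses their statistical coupling with rank-based
    methods: Spearman and partial Spearman correlation with bootstrap
    percentile confidence intervals and Benjamini-Hochberg false-discovery
    control, restricted-cubic-spline regression with Wald nonlinearity tests
    and influence screening, and nonparametric fragmentation-phenotype
    comparisons. Includes a synthetic phantom generator producing cohorts of
    attenuation volumes with known ground truth and tunable rank couplings,
    so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
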