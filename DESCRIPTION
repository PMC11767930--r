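Package: cmtfomics
Title: Coupled Matrix and Tensor Factorization for Microbiome-Metabolome
    Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of stratified microbial functional profiles and
    metabolite intensity tables by coupled matrix and tensor factorization
    (CMTF). A three-way tensor (sample x microbe x pathway) and a matrix
    (sample x metabolite) sharing the sample mode are decomposed into shared
    latent factors, either by alternating least squares or by a weighted
    gradient-based formulation with per-component, per-block weights and
    penalties. Includes compositional preprocessing (logstack scaling of
    stratified pathway abundances, centered log-ratio transformation of
    metabolite intensities), masked-entry cross-validation for rank
    selection, a Mahalanobis/Hotelling test of group separation in latent
    space, loading-based biomarker ranking with top-k hit ratios, synthetic
    coupled-data generators, and readers/writers for HUMAnN3-style
    pathabundance tables and generic TSV feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
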