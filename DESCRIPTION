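Package: vasodomains
Title: Curvature-Domain Mapping with CBV-Sensitive Laminar fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of interleaved VASO (Vascular Space
    Occupancy) and BOLD laminar fMRI acquisitions for mapping mesoscale
    curvature-preference domains in visual cortex. Provides radial-frequency
    stimulus and block-design construction, a parametric cortical-patch
    simulator with ground-truth columnar domains and a surface-biased venous
    weighting, BOLD correction of the nulled series by dynamic division,
    unconvolved GLM activation mapping and block-peak preference maps,
    equi-volume cortical depth analysis with flat-map projection, and
    PCA-collapse modularity quantification with voxel-wise sensitivity and
    specificity indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    png,
    stats,
    utils,
    tools,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
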