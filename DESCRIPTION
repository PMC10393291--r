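Package: gradparc
Title: Functional Parcellation of Cortical Surfaces from Local Connectivity Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fine-grained functional parcellation of triangulated
    cortical surfaces from resting-state functional connectivity. Implements
    second-order connectivity profiles, local-gradient (boundary) mapping via
    watershed flooding on the mesh, gradient-driven spherical surface
    registration, watershed parcellation, an evaluation battery (split-half
    reproducibility, principal-component homogeneity, profile variance,
    rotation null parcellations, spherical Hausdorff distance, patch
    variability maps), parcel-level network clustering with split-half
    stability selection, parcel-wise developmental metrics (homogeneity and
    graph local efficiency trajectories over age sliding windows), and a
    synthetic spherical-cortex cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
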