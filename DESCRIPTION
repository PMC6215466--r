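Package: arealmap
Title: Cortical Areal Parcellation from Resting-State Functional
    Connectivity Boundary Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cohort-level parcellation of a cortical surface mesh from
    resting-state functional connectivity (RSFC) boundary mapping:
    framewise-displacement scrubbing and nuisance cleaning of surface
    BOLD time series, bootstrap-averaged RSFC-similarity gradient maps,
    watershed boundary maps and parcellations, rotation (spin) null
    models for boundary, homogeneity, silhouette, overlap and
    task-agreement statistics, and parcel-graph network analysis with a
    native two-level map-equation community detection, cross-density
    consensus and brain system segregation.  Ships a synthetic-cohort
    generator with planted areal and system structure so every stage of
    the pipeline is testable without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
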