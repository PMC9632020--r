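Package: airwaymorph
Title: Position-Dependent Morphometry of 3D Upper-Airway Filling Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how the air-filled space of the upper airway changes
    between the supine and maximum head-extension positions. From a closed
    triangle surface of the airway filling (STL/PLY/OBJ, or extracted from a
    NIfTI segmentation mask), the package computes the enclosed volume, the
    orthographic silhouette on the coronal, sagittal and horizontal anatomical
    planes as a 1 mm^2 occupancy grid, and a quadrilateral shape descriptor
    set (projected area, transverse and longitudinal radial lengths, lower
    and left corner angles). Paired position-change rates, two-group t-test
    comparisons and noncentral-t power analysis summarise cohorts, and a
    parametric bent-tube phantom generator provides seeded synthetic cohorts
    with analytic ground-truth volumes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'airwaymorph-package.R'
    'cli.R'
    'cohort-stats.R'
    'descriptors.R'
    'mesh-core.R'
    'mesh-io.R'
    'phantoms.R'
    'projection.R'
    'volumetry.R'
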