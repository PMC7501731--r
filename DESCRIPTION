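Package: macquant
Title: Quantification of Hepatic Macrophage Subsets in Multiplex
    Immunofluorescence and Lipid Droplet Volumetry in FIB-SEM Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tiled detection of F4/80-positive macrophages in multi-channel
    immunofluorescence images of liver tissue, marker-threshold classification
    into resident Kupffer cells (CLEC4F+TIM4+), monocyte-derived Kupffer cells
    (CLEC4F+TIM4-) and CLEC4F- macrophages, partition of the tissue into
    Desmin-high and Desmin-low zones with large-vessel exclusion, and
    per-zone subset composition statistics. Also implements the post-processing
    of 3D lipid-droplet probability maps from FIB-SEM volumes: probability
    threshold, removal of small components, morphological opening with a
    spherical structuring element, and volume extraction. A synthetic-data
    module generates both image types with exact ground truth so that every
    stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    tiff,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Classification
RoxygenNote: 7.3.3
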