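Package: activemesh
Title: Active-Mesh Segmentation of 3D Cell Aggregates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of cell nuclei and cell membranes in 3D fluorescence
    volumes of small cell aggregates using deformable triangulated meshes
    (active meshes) coupled to image energies, together with the surrounding
    machinery: erosion-based saturated distance-transform labels for training
    multi-head voxel predictors, distance-transform-driven instance seeding
    with marker watershed, bounding-box cell tracking, Jaccard-index instance
    evaluation, a synthetic two-channel phantom generator with mesh ground
    truth, and TIFF/PLY/OBJ/CSV interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    xml2,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
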