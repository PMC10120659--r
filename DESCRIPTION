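Package: diffeost
Title: Diffeomorphic Metric Mapping Alignment of Spatial Transcriptomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Aligns spatial transcriptomics datasets by large deformation
    diffeomorphic metric mapping (LDDMM). Cell positions are rasterized into
    smooth density images, an affine transform plus a time-varying velocity
    field are solved by steepest gradient descent against a Gaussian-mixture
    robust matching objective that tolerates partially matched tissue and
    imaging artifacts, and the solved map is applied to transform cell
    coordinates between sections or into a 3D reference atlas, including
    lift-over of voxel-level atlas annotations onto single cells. Includes
    alignment-quality statistics (grid and pseudospot aggregation, cosine
    similarity, landmark RMSE, cell-type composition distances and entropy)
    and a synthetic-tissue generator with analytically known deformations
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
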