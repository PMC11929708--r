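Package: fissurept
Title: Sparse Keypoint Segmentation of Lung Fissures from CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Keypoint-based pipeline for segmenting pulmonary fissures in
    thoracic CT. A 3D volume is abstracted into a sparse point cloud using
    either the Foerstner distinctiveness operator or a lightweight 3D
    convolutional pre-segmentation network; the cloud is labeled by
    geometric deep-learning models (PointNet, DGCNN with EdgeConv, and a
    PointTransformer with vector attention) trained on a built-in
    reverse-mode automatic differentiation engine; dense open fissure
    surfaces are reconstructed either by a grid-based Poisson surface
    reconstruction with lung-mask clipping or by a point-cloud-to-mesh
    autoencoder that deforms a planar template mesh. Includes
    surface-distance evaluation (ASSD, SDSD, Hausdorff) with non-assigned
    fissure accounting and a deterministic synthetic-case generator for
    end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
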