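Package: scapmorph
Title: Statistical Shape Modelling and Genomic Prediction of 3D Bone Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A computational pipeline that turns segmented computed-tomography
    bone volumes into corresponded 3D semi-landmarks and heritable shape
    phenotypes. Bone voxels are extracted by Hounsfield thresholding, pose is
    normalized by moment alignment, a surface mesh is built by Delaunay
    tetrahedralization with long-edge pruning (alpha-shape style), and the mesh
    is sparsified into a semi-landmark atlas by a local-volume criterion. Point
    correspondence across individuals is established with the coherent point
    drift algorithm (rigid, affine and non-rigid modes), followed by
    interquartile-range outlier filtering and principal-component analysis of
    the landmark coordinates. Principal-component scores are analysed with
    animal models: pedigree and genomic (VanRaden) relationship matrices,
    restricted maximum likelihood variance components, Henderson's mixed-model
    equations, and eigenanalysis of the genetic-by-phenotypic-inverse
    covariance product. Masked-validation genomic prediction of whole-bone 3D
    shape is scored by mean Euclidean node error and a spatial per-landmark
    prediction reliability, with isonormal scalar fields for visualising shape
    modes. A synthetic-data generator (parametric scapula-like solids, gene
    dropping through simulated pedigrees, latent shape modes with target
    heritabilities) makes every stage testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RANN,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
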