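Package: commonlines
Title: Algebraic Common-Lines Methods for Cryo-EM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with common lines between cryo-electron microscopy
    projection images through a 2n x n block matrix of common-line representatives.
    Provides the algebraic consistency constraints on that matrix (a rank-3 condition
    plus sparse quadratic norm and determinant constraints), robust joint scale
    estimation and denoising by iteratively reweighted least squares with ADMM,
    Sinkhorn-style alternating row and column scaling onto the constraint set,
    recovery of the underlying 3D rotations up to global rotation and handedness,
    and a sampling-based community-detection procedure that sorts discretely
    heterogeneous image sets into homogeneous clusters. Includes synthetic data
    generators, a minimal analytic projection-image pipeline with correlation-based
    common-line detection, and evaluation metrics (Procrustes rotation error,
    scale-invariant denoising error, adjusted Rand index).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    mclust,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
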