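Package: voxmc
Title: Voxel-Based Monte Carlo Photon Transport in Heterogeneous Media
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale Monte Carlo simulator for light transport in 3D
    heterogeneous turbid media defined on a voxel grid. Simulations are
    described by a JSON input dialect (Session/Forward/Optode/Domain/Shapes)
    with typed N-D arrays carried as JData-style annotations (optionally
    zlib-compressed and Base64-encoded). Provides constructive solid geometry
    rasterization to label volumes, a family of source models (pencil,
    isotropic, cone, Gaussian, planar, disk, line, slit, Fourier and pattern
    sources with a focal-length parameter), segment-accurate voxel traversal
    with per-voxel energy deposition, Henyey-Greenstein scattering, four
    bounding-box boundary conditions (absorbing, Fresnel, mirror, cyclic),
    refractive-index mismatch physics, Russian roulette, time-gated fluence
    output, detected-photon records with partial pathlengths, seed-based
    photon replay for Jacobian construction, and split/merge parallel
    execution with reproducible per-photon random substreams.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
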