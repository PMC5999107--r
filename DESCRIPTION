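Package: voxcem
Title: Discrete Particle Simulation of Bone Cement Infiltration in
    Voxelized Open-Cell Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates percutaneous bone-cement augmentation of porous,
    trabecular-bone-like structures.  Cement spread is modelled as a biased
    lattice random walk over the 26-voxel Moore neighbourhood, with injection
    direction encoded as anisotropic step probabilities, cement viscosity as
    the per-iteration jump size, and contact inhibition preventing particles
    from occupying bone or previously settled cement.  Augmented structures
    are scored by voxel-based linear-elastic finite-element compression
    (apparent Young's modulus and its improvement over the unaugmented
    baseline) and by geometric metrics of the cement cloud (volume, surface
    area, Wadell sphericity, connectivity).  Includes a Gaussian-random-field
    generator of open-cell structures at prescribed porosity, MetaImage/TIFF
    volume I/O, and a config-driven study pipeline sweeping structure
    porosity, cement viscosity and injection direction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
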