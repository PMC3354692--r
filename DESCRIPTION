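Package: trabfe
Title: Voxel Coarsening and Micro Finite-Element Analysis of Trabecular Bone
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts binary microCT slice stacks of trabecular bone into
    voxel models, simulates scan-resolution degradation by four coarsening
    schemes (Hexahedral cuberrille majority, First-Last, First-Second and
    First-Third slice pairing), meshes the voxel models with 8-node
    hexahedral elements, solves linear-elastic uniaxial compression to
    obtain the apparent elastic modulus, and computes bone histomorphometry
    indices (BV/TV, Tb.Th, Tb.N, mean layer volume) together with the
    regression machinery relating modulus decay under coarsening to those
    structural indices. Includes deterministic and Gaussian-random-field
    phantom generators emulating femoral-head trabecular cores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
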