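Package: xraydecomp
Title: Decomposition of Musculoskeletal Radiographs into Per-Structure Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the decomposition of single radiographs into
    additive per-structure projection images (bones, individual muscles and a
    residual background). Provides synthetic 3D musculoskeletal phantoms with
    known per-side structure volumes, digitally reconstructed radiograph (DRR)
    rendering under a line-integral attenuation model with exact and sampled
    ray integrators, quantum (Poisson) noise simulation, an unpaired
    cycle-consistent image translation model with hierarchical coarse-to-fine
    generators, patch-based discriminators and a gradient-correlation
    reconstruction loss, and evaluation metrics including PSNR, Dice with
    best-average-threshold selection, an affected/unaffected muscle volume
    ratio and intraclass correlation coefficients.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    RNifti,
    tiff,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
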