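Package: qsrr
Title: Quantitative Structure-Retention Relationship Modelling for PAH Chromatography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete quantitative structure-retention relationship (QSRR)
    workflow for predicting gradient-elution retention times of polycyclic
    aromatic hydrocarbons from 3D molecular descriptors and chromatographic
    run conditions. Builds idealized PAH geometries on a hexagonal lattice or
    reads XYZ/SDF files; computes molecular weight, ring/circuit counts,
    radial distribution function (RDF) and 3D-MoRSE descriptors; generates
    three-level full-factorial designs with cubic-subspace centre points;
    prunes and scales descriptor tables; selects variables by a genetic
    algorithm with leave-one-out cross-validated multilinear-regression
    fitness, by VIP scores, or by covariance selection (CovSel); and fits
    NIPALS partial least squares and backpropagation neural-network retention
    models with venetian-blinds cross-validation, Kennard-Stone duplex
    splitting, early stopping and multi-restart averaging. Includes a
    synthetic-data generator emulating the 16-analyte by 35-condition study
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
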