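Package: osteomech
Title: Multiscale Skeletal Phenotyping from Micro-CT, Nanoindentation and
    Whole-Bone Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for quantitative bone phenotyping of
    mouse femurs and similar long bones. Provides a synthetic phantom
    generator with analytic ground truth (voxel femur and beam phantoms,
    Hertzian force-indentation curves, three-point-bending records,
    calcein double-label tables); trabecular and cortical micro-CT
    morphometry (BV/TV, BS/TV, Tb.N, Tb.Th, Tb.Sp, SMI, Ct.Th) using
    distance-transform local thickness and isosurface areas; per-slice
    cross-sectional second moments of area and geometric bending
    coefficients Imax/C1 and Imin/C2; Hertzian spherical-contact fitting
    of AFM force-indentation curves with frequency-dependence analysis;
    load-displacement metric extraction for three-point bending; a
    voxel-hexahedral linear-elastic finite-element bending solver with
    von Mises stress and strain fields; calcein histomorphometry (MAR,
    MS/BS, BFR/BS) and cell densities; and group statistics including
    delta-delta-Ct expression analysis and cohort phenotype reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
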