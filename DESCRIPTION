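Package: symref
Title: Multi-Symmetry Single-Particle Refinement for Symmetry-Mismatched Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale single-particle cryo-EM refinement toolkit for protein
    complexes whose outer shell is point-group symmetric while the interior is
    asymmetric, modelled on the squid-hemocyanin decamer (a D5 cylindrical wall
    enclosing an asymmetric 20-domain inner collar). Provides MRC2014 volume
    input/output, Cn/Dn point-group symmetrization and orbit analysis, a
    per-iteration reference-adjustment step (wall symmetrization plus collar
    up-weighting), Fourier-slice projection matching with gold-standard
    half-set refinement, FSC resolution estimation, a parametric synthetic
    phantom generator, and the combinatorial assembly model of the decamer
    (ring symmetry break, four protomer conformers, wall-aligned RMSD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    bio3d
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
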