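Package: bilff
Title: All-Atom Force-Field Modelling of Triazolium and Benzoate Ionic Liquids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-contained toolkit for classical all-atom simulations of
    1-ethyl-3-methyl-1,2,3-triazolium and benzoate based ionic liquids with the
    BILFF parameter set (OPLS-AA functional form with geometric combining rules
    and scaled ionic charges of +/-0.82 e). Provides the embedded parameter
    library and molecule templates, an energy and analytic-force evaluator for
    periodic systems (truncated, damped-shifted-force and Ewald electrostatics),
    a compact velocity-Verlet molecular dynamics engine with Berendsen,
    Langevin and Nose-Hoover thermostats, an isotropic Nose-Hoover-style
    barostat and SHAKE/RATTLE constrained rigid water, together with the
    structural and dynamical trajectory analyses used in force-field
    validation: radial distribution functions and peak metrics, coordination
    numbers, combined distance-angle distributions, spatial distribution
    functions, intermittent and continuous hydrogen-bond lifetimes, and
    self-diffusion from mean squared displacements. Includes seeded synthetic
    fixture generators and readers/writers for extended XYZ, PDB, LAMMPS data,
    Gaussian cube and a plain-text parameter-file format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
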