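Package: cgcellulose
Title: Martini 3 Coarse-Grained Models of Cellulose Fibrils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds four-bead-per-glucose coarse-grained models of cellulose
    Ialpha, Ibeta and type-II fibrils, generates the elastic-network bonded
    topology and Martini 3 nonbonded parameter tables, runs Langevin or
    velocity-rescale coarse-grained dynamics with a compiled engine, and
    computes the structural validation statistics used to parameterize such
    models: pair-distance distributions, Kabsch-superposed trajectory RMSD,
    all-frame-pair cross-RMSD between trajectories, and fibril twist
    dihedral statistics.  Includes a bead-type and elastic-constant scan
    that ranks candidate parameter sets by structural deviation, PDB/GRO
    structure and trajectory I/O, a GROMACS-dialect topology writer/reader,
    and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    Rcpp,
    bio3d,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
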