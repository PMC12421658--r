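Package: mdspectra
Title: Replica-Averaged Post-Processing of GROMACS Molecular Dynamics Output
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Parses GROMACS post-processed output files (grace-annotated .xvg
    time series, .xpm colour-coded matrices, whitespace .dat tables), aggregates
    an arbitrary number of simulation replicas by arithmetic mean and sample
    standard deviation, and computes the standard families of molecular-dynamics
    descriptive analyses: time-dependent property profiles (RMSD, RMSF, radius
    of gyration, SASA, hydrogen bonds, salt bridges), Gaussian kernel density
    estimates in one and two dimensions, DSSP secondary-structure probabilities
    and fractions per frame, circular statistics for dihedral angles
    (ligand dihedrals, Ramachandran phi/psi, chi1/chi2 rotamers), protein-ligand
    contact and minimum-distance traces, ligand occupancy maps, inter-residue
    distance-matrix heatmaps, and thermodynamic monitoring. Includes a seeded
    synthetic-data generator emitting GROMACS-dialect files with known ground
    truth, ggplot2 visualisations for every result type, and a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
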