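Package: alloitc
Title: Sets-of-Sites ITC Fitting and Umbrella-Sampling Free Energies for
    Allosteric Ligand Competition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of allosteric competition between ligands binding to
    multi-site proteins such as serum albumin. Implements the independent
    sets-of-sites equilibrium model for isothermal titration calorimetry
    (ITC): forward simulation of titration isotherms with perfusion-cell
    dilution bookkeeping, single-isotherm nonlinear least-squares fitting
    with parameter fixing, and global fitting of isotherm panels with
    shared thermodynamic parameters and a per-isotherm occupancy of the
    high-affinity site. A companion module evaluates geometric collective
    variables (dihedrals, planar angles and distances over atom-group
    centres of mass) on protein structures, runs steered and umbrella-
    sampled overdamped Langevin dynamics on analytic landscapes, and
    reconstructs one-dimensional free-energy profiles with the weighted
    histogram analysis method (WHAM).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    yaml,
    jsonlite,
    bio3d,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
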