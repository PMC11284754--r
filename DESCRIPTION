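Package: starwrap
Title: Coarse-Grained Simulation of Membrane Wrapping of Spiked Nanostars
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An implicit-solvent coarse-grained molecular dynamics toolkit
    for studying receptor-mediated wrapping (endocytosis) of nanoparticles
    by a lipid bilayer. Lipids follow a three-bead parameterization (one
    head, two tail beads; FENE bonds, harmonic angle, WCA excluded volume,
    and a cosine-squared tail attraction replacing explicit solvent).
    Nanoparticles are rigid bead shells: spheres with ligand patches or
    spiked nanostars with ligand-decorated tips. Ligand-receptor adhesion
    uses reversible Morse bonds with a strict one-to-one valence
    constraint, stochastic formation within a capture radius, and
    deterministic breakage beyond an extension limit. Dynamics use a
    Langevin thermostat and a zero-tension barostat in the membrane plane.
    Analysis covers wrapping fraction and wrapping time, binned membrane
    thickness maps, lipid displacement, vesicle membership, particle shape
    metrics (patch separation, solidity), and a transwell apparent
    permeability utility.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    grDevices,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
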