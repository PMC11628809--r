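Package: membranekit
Title: Membrane Biophysics Analysis of NMR Spectra, Cleavage Kinetics, and
    Bilayer Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the membrane-biophysics analysis chain used to study
    how bilayer thickness modulates intramembrane protease activity:
    simulation and dePakeing of deuterium quadrupolar powder spectra with
    extraction of smoothed acyl-chain order-parameter profiles, mean-torque
    projection of order profiles onto acyl chain lengths and
    thickness-versus-cholesterol regressions, decomposition of phosphorus-31
    lineshapes into axially symmetric chemical-shift-anisotropy powder
    patterns, single-exponential fitting of FRET substrate-cleavage progress
    curves, and molecular-dynamics membrane observables (segmental order
    parameters, annular-lipid classification and composition, headgroup and
    helix angles, residue-pair radial distribution functions, and the
    Helfrich-Canham bending modulus from height-fluctuation spectra).
    Seeded synthetic-data generators emulate every input class so the whole
    pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
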