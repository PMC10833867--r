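Package: memscore
Title: Implicit-Membrane Electrostatic Energy Model for Peptides and Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fast implicit-membrane energy model for membrane-protein
    scoring and design evaluation. Computes lipid-bilayer electrostatic
    potential profiles from gridded charge densities with an FFT Poisson
    solver, fits piecewise analytical depth profiles per lipid type,
    evaluates hydration-dependent membrane-dielectric Coulomb energies and
    water-to-bilayer transfer energies with neutral-pH Asp/Glu corrections,
    combines them with fitted weights, samples rigid-body peptide
    orientations over depth, tilt and rotation to locate energy minima, and
    computes design-evaluation metrics (sequence recovery, KL divergence,
    perplexity, confusion matrices) stratified by membrane region.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    bio3d,
    minpack.lm,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
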