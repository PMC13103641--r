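Package: vesiform
Title: Curved-Element Triangulated-Surface Monte Carlo for Peptide-Driven
    Membrane Remodeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An integrative membrane-modeling toolkit built around a
    dynamically triangulated surface (DTS) Monte Carlo simulator with
    curved triangular elements. Edge interpolants of extended Nagata type
    give per-face mean and Gaussian curvature from the full shape
    operator; per-face lipid compositions and integer peptide occupancies
    couple a Helfrich curvature energy with osmotic, stretching, binding
    and ideal-mixing terms, so that curvature sorting of lipids and
    adsorbed cell-penetrating peptides emerges from Metropolis sampling.
    Companion modules extract elastic moduli from molecular-dynamics
    style observables (real-space tilt fluctuations, lateral stress
    profile moments), blend per-lipid material parameters through
    composition and adsorbate mixing rules, calibrate the peptide
    footprint area against lipid demixing on flat patches, and provide
    autocorrelation-corrected error estimates and curvature-resolved
    sorting maps for post-processing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'RcppExports.R'
    'analysis.R'
    'calibration.R'
    'config.R'
    'vesiform-package.R'
    'material.R'
    'surface-mesh.R'
    'membrane-system.R'
    'energy.R'
    'extraction.R'
    'fixtures-data.R'
    'fixtures-mesh.R'
    'mc.R'
    'mesh-io.R'
    'nagata.R'
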