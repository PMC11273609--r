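Package: smfsbd
Title: Single-Molecule Force Spectroscopy Analysis and Rigid-Body
    Brownian Dynamics of Electron-Transfer Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse atomic force microscopy force-distance
    curves from single-molecule force spectroscopy of transient
    electron-transfer complexes, and to simulate the diffusional
    association of a small soluble cytochrome with a membrane-embedded
    reaction-centre complex.  Includes a synthetic force-curve generator
    with per-condition presets, rupture-event detection with
    specific/nonspecific classification, probability-normalised force
    histograms with two-component Gaussian deconvolution, rigid-body
    mechanical and hydrodynamic property calculators, smoothed
    electrostatic and Lennard-Jones potential grids, an overdamped
    rigid-body Brownian dynamics propagator with steered pulling, and
    contact-kinetics, binding-pose clustering and occupancy-based
    affinity analyses of the resulting trajectories.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    bio3d,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
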