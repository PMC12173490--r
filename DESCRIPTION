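Package: ecoliswim
Title: Mesoscale Hydrodynamic Simulation of Escherichia coli Run-and-Tumble Motility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A particle-based model of a swimming Escherichia coli bacterium
    coupled to a dissipative particle dynamics (DPD) solvent. The cell body is
    an elastic triangulated membrane on a superellipsoidal surface with
    worm-like-chain bonds, discrete Helfrich bending elasticity and area/volume
    constraints. Flagella are chains of octahedral segments carrying
    orthonormal material frames with twist/bend elasticity, driven by motor
    torques with body counter-torques, anchored through a hook angle
    potential, and subject to a two-state polymorphic transformation of their
    helical handedness. The package provides builders for all components,
    a velocity-Verlet DPD integrator with fluid-property measurement
    (temperature, shear viscosity), a run/tumble phase scheduler, and
    trajectory analysis of swimming speed, wobbling angle, rotation
    frequencies and tumble angles.
License: MIT + file LICENSE
Encoding: UTF-8
NeedsCompilation: yes
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
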