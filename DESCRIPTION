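Package: valvemech
Title: Constitutive Modelling, Fiber Architecture and Hemodynamic Scoring for Aortic Valve Leaflets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale computational chain for comparing anisotropic
    hyperelastic constitutive laws and rule-based collagen fiber
    architectures of aortic valve leaflets. Implements three
    fiber-reinforced strain-energy functions with incompressible
    plane-stress planar-biaxial responses, bound-constrained calibration
    to biaxial stretch-stress data, Laplace-Dirichlet harmonic fiber
    field generation on triangulated leaflet surfaces, a three-element
    Windkessel afterload model, transvalvular hemodynamic indices
    (regurgitant fraction, mean pressure gradient, effective orifice
    area, energy loss), and a min-max multi-criteria scoring scheme that
    ranks constitutive-law/fiber-architecture combinations. Synthetic
    generators provide biaxial datasets, surrogate cycle waveforms and
    labelled leaflet meshes for testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
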